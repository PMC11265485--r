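# Per-image ROI statistics: noise, CNR, NTD, homogeneity.

#' Define a square ROI
#'
#' @param center pixel coordinates `c(row, col)` of the ROI centre (1-based).
#' @param size side length in pixels (odd sizes centre exactly on a pixel).
#' @param label optional name.
#' @return An object of class `ctiq_roi`.
#' @export
square_roi <- function(center, size, label = "roi") {
  stopifnot(length(center) == 2, size >= 1)
  structure(list(center = round(center), size = as.integer(size),
                 label = label), class = "ctiq_roi")
}

#' Standard ROI layout for the phantom
#'
#' The measurement layout used on every slice: a 41 x 41 px (28.1 mm) ROI at
#' the centre of the homogeneous insert, four 21 x 21 px (14.4 mm) ROIs in
#' its peripheral part at 90 degree spacings, and one 21 x 21 px ROI in the
#' phantom background. The peripheral radius defaults to the largest that
#' keeps each ROI fully inside the insert.
#'
#' @param layout a [ctiq_layout()].
#' @param central_size,peripheral_size ROI side lengths, pixels.
#' @param peripheral_radius distance (mm) from the insert centre to the
#'   peripheral ROI centres; `NULL` picks the largest admissible value.
#' @param background_center background ROI centre `c(x, y)`, mm.
#' @return Named list of [square_roi()]s: `central`, `peripheral1..4`,
#'   `background`, with class `ctiq_roi_set`.
#' @export
roi_set <- function(layout, central_size = 41, peripheral_size = 21,
                    peripheral_radius = NULL, background_center = c(0, 0)) {
  sp <- layout$pixel_spacing
  r_ins <- layout$insert_diameter / 2
  half_diag <- peripheral_size * sp * sqrt(2) / 2
  if (is.null(peripheral_radius)) peripheral_radius <- r_ins - half_diag
  if (peripheral_radius + half_diag > r_ins + 1e-9)
    stop("peripheral ROIs do not fit inside the homogeneous insert")
  if (central_size * sp * sqrt(2) / 2 > r_ins)
    stop("central ROI does not fit inside the homogeneous insert")
  ctr <- layout$insert_center
  rois <- list(central = square_roi(mm_to_px(layout, ctr), central_size,
                                    "central"))
  angles <- c(0, 90, 180, 270) * pi / 180
  for (i in seq_along(angles)) {
    pos <- ctr + peripheral_radius * c(cos(angles[i]), sin(angles[i]))
    rois[[paste0("peripheral", i)]] <-
      square_roi(mm_to_px(layout, pos), peripheral_size,
                 paste0("peripheral", i))
  }
  rois$background <- square_roi(mm_to_px(layout, background_center),
                                peripheral_size, "background")
  structure(rois, class = c("ctiq_roi_set", "list"))
}

#' Extract the pixels of a ROI from one slice
#'
#' Returns the exact pixel block, no interpolation.
#'
#' @param stack an [image_stack()] (or a plain matrix).
#' @param roi a [square_roi()].
#' @param slice slice index.
#' @return A `size x size` numeric matrix.
#' @export
extract_roi <- function(stack, roi, slice = 1) {
  img <- if (inherits(stack, "ctiq_stack")) get_slice(stack, slice) else stack
  half <- (roi$size - 1) %/% 2
  rows <- (roi$center[1] - half):(roi$center[1] - half + roi$size - 1)
  cols <- (roi$center[2] - half):(roi$center[2] - half + roi$size - 1)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(img) ||
      max(cols) > ncol(img))
    stop("ROI '", roi$label, "' exceeds the image bounds")
  img[rows, cols]
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mu1 - mu2) / sigma`, with `mu1` the mean CT number of the
#' homogeneous insert, `mu2` that of the phantom background, and `sigma` the
#' noise (SD) in the insert.
#'
#' @param mu1,mu2 region means, HU.
#' @param sigma noise SD, HU; must be positive.
#' @return CNR, unitless.
#' @export
cnr <- function(mu1, mu2, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be > 0 for CNR")
  (mu1 - mu2) / sigma
}

#' Noise texture deviation (NTD)
#'
#' The fraction of ROI pixels whose CT number deviates from the ROI mean by
#' strictly more than three sample standard deviations,
#' `f_3sigma = #\{i : |p_i - pbar| > 3 sigma\} / n`. For pure Gaussian noise
#' the expected value is `2 (1 - Phi(3)) = 0.0027`; elevated values flag
#' non-Gaussian (blotchy) texture. A constant ROI returns 0.
#'
#' @param pixels numeric vector or matrix of ROI pixel values (>= 2 pixels).
#' @return Fraction in `[0, 1]`.
#' @export
ntd <- function(pixels) {
  p <- as.vector(pixels)
  if (length(p) < 2) stop("NTD needs at least 2 pixels")
  s <- stats::sd(p)
  if (s == 0) return(0)
  mean(abs(p - mean(p)) > 3 * s)
}

#' Homogeneity
#'
#' Maximum difference among the mean CT numbers of the ROIs in the
#' homogeneous insert.
#'
#' @param roi_means vector of >= 2 ROI means, HU.
#' @return `max - min`, HU.
#' @export
homogeneity <- function(roi_means) {
  if (length(roi_means) < 2) stop("homogeneity needs at least 2 ROI means")
  max(roi_means) - min(roi_means)
}

#' Compare two groups of metric values
#'
#' Welch two-sample t-test (two-sided), flagged at the 5% level. Two
#' zero-variance groups with equal means give `t = 0, p = 1`.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @return `list(t, p, significant)`.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, p = 1, significant = FALSE))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf, p = 0,
                significant = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05)
}

# summary statistics of one pixel block
roi_stats <- function(pixels) {
  p <- as.vector(pixels)
  list(mean = mean(p), sd = stats::sd(p), ntd = ntd(p), n = length(p))
}

#' Per-slice ROI metrics of a stack
#'
#' Applies the ROI layout to every slice and tabulates noise (central insert
#' ROI SD), insert and background means, CNR, NTD and homogeneity. NTD is the
#' average over the five insert ROIs by default (set `ntd_rois = "central"`
#' for the central ROI only); homogeneity is the range of the five insert ROI
#' means.
#'
#' @param stack an [image_stack()].
#' @param rois a [roi_set()].
#' @param ntd_rois `"insert"` (all five insert ROIs) or `"central"`.
#' @return A data frame with one row per slice.
#' @export
stack_metrics <- function(stack, rois, ntd_rois = c("insert", "central")) {
  ntd_rois <- match.arg(ntd_rois)
  insert_names <- c("central", paste0("peripheral", 1:4))
  ns <- n_slices(stack)
  out <- vector("list", ns)
  for (k in seq_len(ns)) {
    stats_k <- lapply(rois[insert_names], function(r)
      roi_stats(extract_roi(stack, r, k)))
    bg <- roi_stats(extract_roi(stack, rois$background, k))
    central <- stats_k$central
    ntd_val <- if (ntd_rois == "central") central$ntd else
      mean(vapply(stats_k, `[[`, numeric(1), "ntd"))
    out[[k]] <- data.frame(
      scan_id = stack$scan_id, algorithm = stack$algorithm,
      dose = stack$dose_ctdi, thickness = stack$slice_thickness, slice = k,
      insert_mean = central$mean, background_mean = bg$mean,
      noise = central$sd,
      cnr = cnr(central$mean, bg$mean, central$sd),
      ntd = ntd_val,
      homogeneity = homogeneity(vapply(stats_k, `[[`, numeric(1), "mean")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Aggregate per-slice metrics by condition
#'
#' Means and SDs of noise, CNR and NTD over all slices of all repeat scans in
#' each (algorithm, dose, thickness) cell, the homogeneity range, and the
#' relative CNR of each cell against a named baseline algorithm within the
#' same dose level.
#'
#' @param metrics per-slice data frame from [stack_metrics()] (rows of
#'   several stacks concatenated).
#' @param baseline baseline algorithm label for relative CNR.
#' @param baseline_thickness thickness of the baseline arm; default: same
#'   thickness as the cell being compared.
#' @return A data frame with one row per condition.
#' @export
aggregate_metrics <- function(metrics, baseline = "FBP",
                              baseline_thickness = NULL) {
  cells <- unique(metrics[, c("algorithm", "dose", "thickness")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- metrics$algorithm == cells$algorithm[i] &
      metrics$dose == cells$dose[i] & metrics$thickness == cells$thickness[i]
    m <- metrics[sel, ]
    data.frame(
      algorithm = cells$algorithm[i], dose = cells$dose[i],
      thickness = cells$thickness[i], n_slices = nrow(m),
      noise_mean = mean(m$noise), noise_sd = stats::sd(m$noise),
      cnr_mean = mean(m$cnr), cnr_sd = stats::sd(m$cnr),
      ntd_mean = mean(m$ntd), ntd_sd = stats::sd(m$ntd),
      homogeneity_min = min(m$homogeneity),
      homogeneity_max = max(m$homogeneity), stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, rows)
  agg$noise_sd[is.na(agg$noise_sd)] <- 0
  agg$cnr_sd[is.na(agg$cnr_sd)] <- 0
  agg$ntd_sd[is.na(agg$ntd_sd)] <- 0
  agg$relative_cnr <- NA_real_
  for (i in seq_len(nrow(agg))) {
    bt <- if (is.null(baseline_thickness)) agg$thickness[i] else
      baseline_thickness
    ref <- agg$cnr_mean[agg$algorithm == baseline & agg$dose == agg$dose[i] &
                          agg$thickness == bt]
    if (length(ref) != 1)
      stop("baseline '", baseline, "' missing for dose level ", agg$dose[i],
           " at thickness ", bt, " mm")
    agg$relative_cnr[i] <- agg$cnr_mean[i] / ref
  }
  agg[order(agg$algorithm, agg$thickness, agg$dose), ]
}
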