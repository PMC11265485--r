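# Noise power spectrum estimation: 2D periodogram over homogeneous ROIs,
# radial average, normalization, and the average spatial frequency.

detrend_roi <- function(roi, method) {
  switch(method,
         none = roi,
         mean = roi - mean(roi),
         poly1 = {
           # first-order polynomial surface: removes mean and linear
           # gradients (the anthropomorphic background is not perfectly flat)
           nr <- nrow(roi); nc <- ncol(roi)
           x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
           y <- matrix(seq_len(nr), nr, nc)
           fit <- stats::lm.fit(cbind(1, as.vector(x), as.vector(y)),
                                as.vector(roi))
           matrix(fit$residuals, nr, nc)
         },
         stop("unknown detrend method: ", method))
}

#' 2D noise power spectrum of a set of ROIs
#'
#' Each ROI is detrended and discrete-Fourier-transformed;
#' `NPS(u, v) = (dx * dy) / (Nx * Ny) * <|DFT|^2>` averaged over all ROIs.
#' With this normalization the spectrum of white noise of variance
#' `sigma^2` has flat level `dx * dy * sigma^2` (HU^2 mm^2), and the 2D
#' Parseval identity `sum(NPS) * du * dv = detrended pixel variance` holds.
#'
#' @param rois list of >= 4 square pixel matrices, all the same size.
#' @param spacing pixel spacing, mm.
#' @param detrend `"poly1"` (default: subtract a first-order polynomial
#'   surface per ROI), `"mean"`, or `"none"`.
#' @return An object of class `ctiq_nps2d`: the (unshifted) spectrum matrix,
#'   spacing, ROI count/size, detrend tag, and the mean detrended pixel
#'   variance.
#' @export
nps_2d <- function(rois, spacing, detrend = c("poly1", "mean", "none")) {
  detrend <- match.arg(detrend)
  if (length(rois) < 4) stop("NPS estimation needs at least 4 ROIs")
  w <- nrow(rois[[1]])
  ok <- vapply(rois, function(r) is.matrix(r) && nrow(r) == w &&
                 ncol(r) == w, logical(1))
  if (!all(ok)) stop("all ROIs must be square matrices of identical size")
  acc <- matrix(0, w, w)
  var_acc <- 0
  for (r in rois) {
    d <- detrend_roi(r, detrend)
    acc <- acc + Mod(stats::fft(d))^2
    var_acc <- var_acc + sum(d^2) / length(d)  # mean square about the trend
  }
  nps <- spacing^2 / w^2 * acc / length(rois)
  structure(list(nps2d = nps, spacing = spacing, roi_size = w,
                 n_rois = length(rois), detrend = detrend,
                 roi_var = var_acc / length(rois)),
            class = "ctiq_nps2d")
}

#' Radially average a 2D NPS
#'
#' Bins the 2D frequency samples by radius `sqrt(u^2 + v^2)` into bins of one
#' DFT bin width `1 / (w * dx)`; the bin value is the mean of the
#' contributing samples. The axis spans `[0, Nyquist]`; corner samples beyond
#' Nyquist and empty bins are dropped.
#'
#' @param nps2d a `ctiq_nps2d` from [nps_2d()], or a square matrix (then
#'   `spacing` must be given).
#' @param spacing pixel spacing, mm (taken from the object when omitted).
#' @return A data frame `(freq, nps)` with frequencies in cycles/mm.
#' @export
radial_average <- function(nps2d, spacing = NULL) {
  if (inherits(nps2d, "ctiq_nps2d")) {
    spacing <- nps2d$spacing
    mat <- nps2d$nps2d
  } else mat <- nps2d
  if (is.null(spacing)) stop("spacing required")
  w <- nrow(mat)
  if (ncol(mat) != w) stop("radial averaging requires a square spectrum")
  df <- 1 / (w * spacing)
  f_n <- 1 / (2 * spacing)
  fr <- fft_freqs(w, spacing)
  r <- sqrt(outer(fr^2, fr^2, "+"))
  bin <- round(r / df)
  keep <- bin * df <= f_n + 1e-12
  vals <- tapply(mat[keep], bin[keep], mean)
  data.frame(freq = as.numeric(names(vals)) * df,
             nps = as.numeric(vals), row.names = NULL)
}

#' Average 1D NPS curves across repeat scans and normalize
#'
#' Arithmetic mean of the per-scan radial profiles (averaging first, then
#' normalizing), then `nNPS = NPS / sum(NPS * df)` so the normalized curve
#' integrates to one over frequency. The total noise power reported is the
#' 2D Parseval integral, i.e. the detrended pixel variance captured by the
#' spectra.
#'
#' @param curves list of per-scan data frames `(freq, nps)` on a common axis.
#' @param total_power per-scan total power (HU^2); averaged alongside.
#' @param n_rois ROI count bookkeeping.
#' @param detrend detrend method tag.
#' @return An object of class `ctiq_nps` with fields `freq_axis`, `nps1d`,
#'   `nnps1d`, `total_power`, `f_avg`, `n_rois`, `detrend`.
#' @export
normalize_and_average <- function(curves, total_power = NA_real_,
                                  n_rois = NA_integer_, detrend = "poly1") {
  if (!length(curves)) stop("no NPS curves supplied")
  freq <- curves[[1]]$freq
  for (c2 in curves)
    if (length(c2$freq) != length(freq) || any(abs(c2$freq - freq) > 1e-9))
      stop("NPS curves are on different frequency axes")
  nps <- Reduce(`+`, lapply(curves, `[[`, "nps")) / length(curves)
  df <- freq[2] - freq[1]
  total <- sum(nps) * df
  if (total <= 0) stop("zero total power; cannot normalize NPS")
  structure(list(freq_axis = freq, nps1d = nps, nnps1d = nps / total,
                 total_power = mean(total_power), f_avg = f_avg(freq, nps),
                 n_rois = n_rois, detrend = detrend),
            class = "ctiq_nps")
}

#' Average spatial frequency of a 1D NPS
#'
#' Power-weighted mean frequency, `sum(f * NPS(f)) / sum(NPS(f))` over the
#' radial bins. Lower values indicate coarser/smoother noise texture.
#'
#' @param freq_axis frequencies, cycles/mm.
#' @param nps1d spectral values (>= 0, not all zero).
#' @return Average frequency, cycles/mm.
#' @export
f_avg <- function(freq_axis, nps1d) {
  if (length(freq_axis) != length(nps1d)) stop("axis/spectrum length mismatch")
  s <- sum(nps1d)
  if (s <= 0) stop("all-zero spectrum has no average frequency")
  sum(freq_axis * nps1d) / s
}

#' Estimate the NPS of repeat scans of a condition
#'
#' Extracts four quadratic ROIs (quadrant arrangement inside the homogeneous
#' insert) from every slice of each scan, forms one radial NPS per scan, and
#' averages across the repeat scans. Convenience wrapper around [nps_2d()],
#' [radial_average()] and [normalize_and_average()].
#'
#' @param stacks list of repeat-scan [image_stack()]s (one is fine).
#' @param layout the [ctiq_layout()] the stacks were imaged/simulated with.
#' @param roi_size NPS ROI side, pixels (default 32).
#' @param roi_offset quadrant offset (mm) of the four ROI centres from the
#'   insert centre along both axes; `NULL` picks the largest admissible value.
#' @param detrend see [nps_2d()].
#' @return A `ctiq_nps` object.
#' @export
estimate_nps <- function(stacks, layout, roi_size = 32, roi_offset = NULL,
                         detrend = "poly1") {
  if (inherits(stacks, "ctiq_stack")) stacks <- list(stacks)
  sp <- layout$pixel_spacing
  half_diag <- roi_size * sp * sqrt(2) / 2
  r_ins <- layout$insert_diameter / 2
  if (is.null(roi_offset)) roi_offset <- (r_ins - half_diag) / sqrt(2)
  if (sqrt(2) * roi_offset + half_diag > r_ins + 1e-9)
    stop("NPS ROIs do not fit inside the homogeneous insert")
  ctr <- layout$insert_center
  centers <- list(ctr + roi_offset * c(1, 1), ctr + roi_offset * c(-1, 1),
                  ctr + roi_offset * c(1, -1), ctr + roi_offset * c(-1, -1))
  rois <- lapply(centers, function(p)
    square_roi(mm_to_px(layout, p), roi_size, "nps"))
  per_scan <- lapply(stacks, function(st) {
    blocks <- list()
    for (k in seq_len(n_slices(st)))
      for (r in rois) blocks[[length(blocks) + 1]] <- extract_roi(st, r, k)
    n2 <- nps_2d(blocks, sp, detrend)
    list(curve = radial_average(n2),
         power = sum(n2$nps2d) / (n2$roi_size * sp)^2,
         n = n2$n_rois)
  })
  normalize_and_average(lapply(per_scan, `[[`, "curve"),
                        total_power = vapply(per_scan, `[[`, numeric(1), "power"),
                        n_rois = sum(vapply(per_scan, `[[`, numeric(1), "n")),
                        detrend = detrend)
}

#' @export
print.ctiq_nps <- function(x, ...) {
  cat(sprintf("ctiq NPS: %d radial bins to %.3g /mm, f_avg %.4g /mm, total power %.4g HU^2 (%s detrend, %s ROIs)\n",
              length(x$freq_axis), max(x$freq_axis), x$f_avg, x$total_power,
              x$detrend, format(x$n_rois)))
  invisible(x)
}

#' @export
plot.ctiq_nps <- function(x, normalized = TRUE, ...) {
  y <- if (normalized) x$nnps1d else x$nps1d
  plot(x$freq_axis, y, type = "l", xlab = "spatial frequency (1/mm)",
       ylab = if (normalized) "nNPS (mm)" else "NPS (HU^2 mm^2)", ...)
  abline(v = x$f_avg, lty = 2)
  invisible(x)
}
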