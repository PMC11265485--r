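# Task-based transfer function by the circular-edge method: radial ESF of
# the low-contrast lesion, differentiated to an LSF, Fourier-transformed and
# normalized to give the TTF and its half-maximum frequency f50.

# linearly interpolated first downward crossing of 0.5; NA when the curve
# never falls below 0.5 within the measured band (distinct from an error)
half_max_crossing <- function(freq, ttf) {
  below <- which(ttf < 0.5)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(freq[1])
  freq[i - 1] + (0.5 - ttf[i - 1]) * (freq[i] - freq[i - 1]) /
    (ttf[i] - ttf[i - 1])
}

#' Locate the lesion centre at subpixel precision
#'
#' Estimates the local background as the median of an annulus around the
#' expected lesion position, thresholds at half the lesion contrast inside a
#' search disk, and returns the contrast-weighted centroid of the
#' supra-threshold pixels. Works for hyper- and hypo-attenuating lesions.
#'
#' @param image a 2D matrix (use the noiseless render or an average over the
#'   lesion slices for noisy data).
#' @param approx_center approximate centre, pixel `c(row, col)`.
#' @param approx_radius approximate lesion radius, pixels.
#' @return Numeric `c(row, col)`, subpixel.
#' @export
find_center <- function(image, approx_center, approx_radius) {
  nr <- nrow(image); nc <- ncol(image)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rows - approx_center[1])^2 + (cols - approx_center[2])^2)
  search <- d <= 1.5 * approx_radius
  annulus <- d > 1.8 * approx_radius & d <= 2.4 * approx_radius
  bg <- stats::median(image[annulus])
  core <- stats::median(image[d <= 0.5 * approx_radius])
  contrast <- core - bg
  if (abs(contrast) < 5)
    stop("no lesion found: contrast below 5 HU at the expected position")
  signal <- (image - bg) * sign(contrast)
  above <- search & signal > abs(contrast) / 2
  if (!any(above)) stop("no pixels above the half-contrast threshold")
  w <- signal[above]
  c(row = sum(rows[above] * w) / sum(w),
    col = sum(cols[above] * w) / sum(w))
}

#' Radial edge spread function of the lesion
#'
#' Pools the pixels of the given slices, bins them by radial distance from
#' the centre, and returns the mean HU per bin ordered inside to outside.
#' Empty bins (possible in the innermost annuli where few pixel centres
#' fall) are filled by linear interpolation; if more than `max_empty_frac`
#' of the bins are empty the ESF is rejected, naming the first empty bin.
#'
#' @param stack an [image_stack()] or a single matrix.
#' @param center subpixel centre `c(row, col)` from [find_center()].
#' @param r_max maximum radius, mm; keep below twice the lesion radius so
#'   neighbouring structures stay out of the profile.
#' @param bin_width radial bin width, mm; default a quarter pixel
#'   (standard circular-edge oversampling).
#' @param slices slice indices to pool; default all.
#' @param max_empty_frac tolerated fraction of empty bins.
#' @return A data frame `(r, esf, n)`: bin centre (mm), mean HU, pixel count.
#' @export
radial_esf <- function(stack, center, r_max, bin_width = NULL, slices = NULL,
                       max_empty_frac = 0.1) {
  if (inherits(stack, "ctiq_stack")) {
    spacing <- stack$pixel_spacing
    if (is.null(slices)) slices <- seq_len(n_slices(stack))
    imgs <- lapply(slices, function(k) get_slice(stack, k))
  } else {
    stop("radial_esf needs a ctiq_stack (pixel spacing required)")
  }
  if (is.null(bin_width)) bin_width <- 0.25 * spacing
  nr <- nrow(imgs[[1]]); nc <- ncol(imgs[[1]])
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r_mm <- sqrt((rows - center[1])^2 + (cols - center[2])^2) * spacing
  sel <- r_mm <= r_max
  bin <- floor(r_mm[sel] / bin_width)
  vals <- unlist(lapply(imgs, function(im) im[sel]))
  bins_rep <- rep(bin, times = length(imgs))
  n_bins <- floor(r_max / bin_width) + 1
  sums <- tapply(vals, factor(bins_rep, levels = 0:(n_bins - 1)), sum)
  cnts <- tapply(rep(1, length(vals)), factor(bins_rep, levels = 0:(n_bins - 1)),
                 sum)
  cnts[is.na(cnts)] <- 0
  esf <- as.numeric(sums) / as.numeric(cnts)
  empty <- which(cnts == 0)
  if (length(empty) > max_empty_frac * n_bins)
    stop("too many empty radial bins; first empty bin index: ", empty[1])
  r_centers <- (0:(n_bins - 1) + 0.5) * bin_width
  if (length(empty)) {
    filled <- which(cnts > 0)
    esf[empty] <- stats::approx(r_centers[filled], esf[filled],
                                xout = r_centers[empty], rule = 2)$y
  }
  data.frame(r = r_centers, esf = esf, n = as.numeric(cnts))
}

#' Turn an ESF into a task-based transfer function
#'
#' Optionally regularizes the noisy ESF to be monotone (isotonic pooling in
#' the direction of the contrast), differentiates it by central finite
#' differences to the LSF, applies a Hann taper centred on the LSF peak,
#' zero-pads, and takes the Fourier magnitude normalized to 1 at zero
#' frequency. `f50` is the linearly interpolated first downward crossing of
#' 0.5; if the TTF never falls below 0.5 within the measured band, `f50` is
#' `NA` and `f50_reached` is `FALSE` (distinct from an error).
#'
#' @param esf data frame `(r, esf)` from [radial_esf()].
#' @param contrast lesion contrast, HU (inner minus outer plateau); estimated
#'   from the profile ends when `NULL`.
#' @param monotone apply isotonic conditioning (recommended for noisy data).
#' @param pad_factor zero-padding factor for the DFT of the LSF.
#' @param correct_sampling divide the measured curve by the known transfer
#'   functions of the radial bin average (boxcar of one bin width) and the
#'   central-difference differentiator, removing their high-frequency
#'   roll-off (default `TRUE`).
#' @return An object of class `ctiq_ttf` with fields `esf`, `lsf`,
#'   `freq_axis`, `ttf`, `f50`, `f50_reached`, `contrast`, `n_slices`.
#' @export
esf_to_ttf <- function(esf, contrast = NULL, monotone = FALSE,
                       pad_factor = 8, correct_sampling = TRUE) {
  r <- esf$r; y <- esf$esf
  n <- length(r)
  if (n < 8) stop("ESF has too few bins")
  m <- max(3, round(0.15 * n))
  if (is.null(contrast)) contrast <- mean(y[1:m]) - mean(y[(n - m + 1):n])
  if (!is.finite(contrast) || contrast == 0)
    stop("lesion contrast is zero; TTF undefined")
  sgn <- sign(contrast)
  if (monotone) {
    # sgn * esf decreases outward; isotonic fit of the increasing negative
    iso <- stats::isoreg(r, -sgn * y)
    y <- -sgn * iso$yf
  }
  dr <- r[2] - r[1]
  lsf <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) / dr
  # taper the LSF tails with a Hann roll-off centred on the peak: flat over
  # the inner half of the symmetric window (so the edge core is untouched),
  # cosine to zero over the outer half
  peak <- which.max(abs(lsf))
  near <- max(min(peak - 1, n - peak), 1)
  frac <- pmin(abs(seq_len(n) - peak) / near, 1)
  taper <- ifelse(frac <= 0.5, 1, 0.5 * (1 + cos(2 * pi * (frac - 0.5))))
  lsf_w <- lsf * taper
  n_pad <- max(256, pad_factor * n)
  padded <- c(lsf_w, rep(0, n_pad - n))
  spec <- Mod(stats::fft(padded))
  if (spec[1] == 0) stop("degenerate LSF: zero area")
  n_keep <- floor(n_pad / 2) + 1
  ttf <- spec[1:n_keep] / spec[1]
  freq <- (0:(n_keep - 1)) / (n_pad * dr)
  if (correct_sampling) {
    sincf <- function(x) ifelse(x == 0, 1, sin(x) / x)
    # bin-average boxcar (width dr) and central-difference differentiator
    resp <- sincf(pi * freq * dr) * sincf(2 * pi * freq * dr)
    ttf <- ttf / pmax(resp, 0.2)
  }
  f50 <- half_max_crossing(freq, ttf)
  structure(list(esf = data.frame(r = r, esf = y),
                 lsf = data.frame(r = r, lsf = lsf),
                 freq_axis = freq, ttf = ttf, f50 = f50,
                 f50_reached = !is.na(f50),
                 contrast = contrast, n_slices = attr(esf, "n_slices")),
            class = "ctiq_ttf")
}

#' Average TTF curves across repeat scans
#'
#' Pointwise mean of the curves on a common frequency axis; `f50` is
#' recomputed on the averaged curve.
#'
#' @param results list of `ctiq_ttf` objects.
#' @return A `ctiq_ttf` object.
#' @export
ttf_average <- function(results) {
  if (!length(results)) stop("no TTF curves supplied")
  freq <- results[[1]]$freq_axis
  for (r in results)
    if (length(r$freq_axis) != length(freq) ||
        any(abs(r$freq_axis - freq) > 1e-9))
      stop("TTF curves are on different frequency axes")
  ttf <- Reduce(`+`, lapply(results, `[[`, "ttf")) / length(results)
  f50 <- half_max_crossing(freq, ttf)
  structure(list(esf = NULL, lsf = NULL, freq_axis = freq, ttf = ttf,
                 f50 = f50, f50_reached = !is.na(f50),
                 contrast = mean(vapply(results, `[[`, numeric(1), "contrast")),
                 n_slices = sum(vapply(results, function(r)
                   r$n_slices %||% 0, numeric(1)))),
            class = "ctiq_ttf")
}

#' Measure the TTF of a scan's low-contrast lesion
#'
#' Finds the lesion centre on the average of the lesion-bearing slices,
#' pools those slices into a radial ESF (default 10 central lesion slices,
#' radius capped at 1.8 lesion radii to keep neighbouring structures out),
#' and converts to a TTF.
#'
#' @param stack an [image_stack()].
#' @param layout the [ctiq_layout()] describing the lesion geometry.
#' @param n_slices_used number of central lesion slices to pool.
#' @param r_max_factor `r_max` as a multiple of the lesion radius.
#' @param monotone passed to [esf_to_ttf()].
#' @return A `ctiq_ttf` object.
#' @export
estimate_ttf <- function(stack, layout, n_slices_used = 10,
                         r_max_factor = 1.8, monotone = TRUE) {
  les <- lesion_slices(layout, n_slices(stack), stack$slice_thickness)
  if (!length(les)) stop("stack has no lesion-bearing slices")
  if (length(les) > n_slices_used) {
    mid <- (length(les) + 1) / 2
    les <- les[order(abs(seq_along(les) - mid))][seq_len(n_slices_used)]
    les <- sort(les)
  }
  avg <- Reduce(`+`, lapply(les, function(k) get_slice(stack, k))) /
    length(les)
  sp <- stack$pixel_spacing
  lesion_r_px <- layout$lesion_diameter / 2 / sp
  ctr <- find_center(avg, mm_to_px(layout, layout$lowc_center), lesion_r_px)
  esf <- radial_esf(stack, ctr, r_max = r_max_factor * layout$lesion_diameter / 2,
                    slices = les)
  attr(esf, "n_slices") <- length(les)
  esf_to_ttf(esf, monotone = monotone)
}

#' @export
print.ctiq_ttf <- function(x, ...) {
  f50 <- x$f50
  cat(sprintf("ctiq TTF: contrast %.3g HU, f50 %s\n", x$contrast,
              if (is.na(f50)) "not reached within the measured band"
              else sprintf("%.4g /mm", f50)))
  invisible(x)
}

#' @export
plot.ctiq_ttf <- function(x, xlim = c(0, 1.2), ...) {
  plot(x$freq_axis, x$ttf, type = "l", xlim = xlim, ylim = c(0, 1.05),
       xlab = "spatial frequency (1/mm)", ylab = "TTF", ...)
  abline(h = 0.5, lty = 3)
  if (!is.na(x$f50)) abline(v = x$f50, lty = 2)
  invisible(x)
}
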