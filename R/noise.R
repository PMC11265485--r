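# Colored-noise synthesis with a prescribed radial noise power spectrum.

# DFT frequency axis (cycles/mm), numpy-fftfreq convention, unshifted
fft_freqs <- function(n, spacing) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * spacing)
}

# radial NPS shape families (unnormalized). "fbp-like" and "ir-like" share
# the ramp-times-Gaussian form f * exp(-(f/f_c)^2); IR textures are simply
# obtained with a smaller f_c (coarser texture, lower f_avg).
nps_shape_value <- function(f, family, f_c = NULL) {
  switch(family,
         "white" = rep(1, length(f)),
         "fbp-like" = ,
         "ir-like" = {
           if (is.null(f_c) || !is.finite(f_c) || f_c <= 0)
             stop("f_c must be > 0 for the '", family, "' shape family")
           f * exp(-(f / f_c)^2)
         },
         stop("unknown NPS shape family: ", family))
}

#' Analytic average spatial frequency of an NPS shape
#'
#' Power-weighted mean frequency of the band-limited radial shape,
#' `integral(f * S(f)) / integral(S(f))` over `[0, Nyquist]`. This is the
#' population value that the radially averaged spectrum of synthesized noise
#' estimates, and the quantity [calibrate_shape()] inverts.
#'
#' @param family one of `"white"`, `"fbp-like"`, `"ir-like"`.
#' @param f_c shape parameter (cycles/mm); ignored for `"white"`.
#' @param spacing pixel spacing, mm (sets the Nyquist frequency).
#' @return Average frequency, cycles/mm.
#' @export
analytic_favg <- function(family, f_c = NULL, spacing) {
  f_n <- 1 / (2 * spacing)
  if (family == "white") return(f_n / 2)
  num <- stats::integrate(function(f) f * nps_shape_value(f, family, f_c),
                          0, f_n, rel.tol = 1e-10)$value
  den <- stats::integrate(function(f) nps_shape_value(f, family, f_c),
                          0, f_n, rel.tol = 1e-10)$value
  num / den
}

#' Calibrate an NPS shape parameter for a target average frequency
#'
#' Solves, by bisection, for the shape parameter `f_c` such that the analytic
#' band-limited average frequency of the family equals `target_favg` to within
#' `tol`. Used to make the simulator hit prescribed texture values (e.g. an
#' FBP-like 0.30 cycles/mm or an IR-like 0.19 cycles/mm).
#'
#' @param target_favg desired average frequency, cycles/mm; must lie strictly
#'   between 0 and the Nyquist frequency.
#' @param family shape family; for `"white"` the average frequency is fixed at
#'   Nyquist/2 and no parameter exists.
#' @param spacing pixel spacing, mm.
#' @param tol convergence tolerance on the average frequency, cycles/mm.
#' @return `f_c` (cycles/mm); `NA_real_` for the parameter-free white family.
#' @export
calibrate_shape <- function(target_favg, family = "fbp-like", spacing,
                            tol = 1e-4) {
  f_n <- 1 / (2 * spacing)
  if (!is.finite(target_favg) || target_favg <= 0 || target_favg >= f_n)
    stop("target_favg must lie in (0, Nyquist = ", signif(f_n, 4), ")")
  if (family == "white") {
    if (abs(target_favg - f_n / 2) > tol)
      stop("white noise has fixed f_avg = Nyquist/2 = ", signif(f_n / 2, 4),
           "; target ", target_favg, " is unattainable")
    return(NA_real_)
  }
  g <- function(fc) analytic_favg(family, fc, spacing) - target_favg
  lo <- 1e-4 * f_n
  hi <- 50 * f_n
  if (g(lo) > 0 || g(hi) < 0)
    stop("target f_avg ", target_favg,
         " is unattainable for family '", family, "'")
  for (i in 1:120) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  fc <- (lo + hi) / 2
  if (abs(analytic_favg(family, fc, spacing) - target_favg) > tol)
    stop("bisection failed to reach tolerance for target ", target_favg)
  fc
}

#' Reconstruction-algorithm noise model
#'
#' Bundles the measurable noise signature the simulator uses to emulate a
#' reconstruction algorithm: a reference noise magnitude with power-law dose
#' and slice-thickness scaling, a radial NPS shape (texture), a point-spread
#' Gaussian applied to the noiseless structure (edge blur), and optionally
#' sparse non-Gaussian "blotch" artifacts of the kind iterative
#' reconstruction produces.
#'
#' Noise magnitude at dose `D` (mGy) and slice thickness `t` (mm) is
#' `sigma_ref * (D / d_ref)^dose_exponent * (t / thickness_ref)^thickness_exponent`;
#' the default exponents of -1/2 are the quantum-noise expectation.
#'
#' @param label algorithm name (e.g. `"FBP"`, `"IR50"`, `"DLH"`).
#' @param sigma_ref noise SD (HU) at the reference dose and thickness.
#' @param d_ref reference dose, mGy.
#' @param dose_exponent,thickness_exponent power-law exponents (unitless).
#' @param thickness_ref reference slice thickness, mm.
#' @param nps_family radial NPS shape family, see [nps_shape_value()].
#' @param f_c shape parameter (cycles/mm); alternatively give `target_favg`.
#' @param target_favg if supplied, `f_c` is calibrated via [calibrate_shape()]
#'   at pixel spacing `spacing`.
#' @param spacing pixel spacing used for calibration, mm.
#' @param blotch `NULL`, or `list(density, amplitude, width)`: blotches per
#'   mm^2, bump amplitude in HU at reference dose/thickness (scaled with the
#'   same power laws as noise), and Gaussian bump width (SD) in mm.
#' @param edge_blur_sigma SD (mm) of the Gaussian blur applied to the
#'   noiseless structure before noise is added; 0 disables blurring.
#' @return An object of class `ctiq_noise_model`.
#' @export
noise_model <- function(label, sigma_ref, d_ref = 25,
                        dose_exponent = -0.5, thickness_exponent = -0.5,
                        thickness_ref = 2.5,
                        nps_family = c("fbp-like", "ir-like", "white"),
                        f_c = NULL, target_favg = NULL, spacing = 0.6854,
                        blotch = NULL, edge_blur_sigma = 0) {
  nps_family <- match.arg(nps_family)
  if (!is.finite(sigma_ref) || sigma_ref <= 0) stop("sigma_ref must be > 0")
  if (!is.finite(d_ref) || d_ref <= 0) stop("d_ref must be > 0")
  if (!is.null(target_favg))
    f_c <- calibrate_shape(target_favg, nps_family, spacing)
  if (nps_family != "white" && (is.null(f_c) || f_c <= 0))
    stop("f_c (or target_favg) must be supplied and > 0 for family '",
         nps_family, "'")
  if (!is.null(blotch)) {
    need <- c("density", "amplitude", "width")
    miss <- setdiff(need, names(blotch))
    if (length(miss)) stop("blotch missing field(s): ", paste(miss, collapse = ", "))
    if (any(unlist(blotch[need]) <= 0)) stop("blotch parameters must be > 0")
  }
  structure(list(label = label, sigma_ref = sigma_ref, d_ref = d_ref,
                 dose_exponent = dose_exponent,
                 thickness_exponent = thickness_exponent,
                 thickness_ref = thickness_ref,
                 nps_family = nps_family, f_c = f_c,
                 blotch = blotch, edge_blur_sigma = edge_blur_sigma),
            class = "ctiq_noise_model")
}

#' @export
print.ctiq_noise_model <- function(x, ...) {
  cat(sprintf("ctiq noise model '%s': sigma %.3g HU @ %g mGy / %g mm (D^%g, t^%g)\n",
              x$label, x$sigma_ref, x$d_ref, x$thickness_ref,
              x$dose_exponent, x$thickness_exponent))
  cat(sprintf("  NPS family %s%s, edge blur %.3g mm, blotch %s\n", x$nps_family,
              if (is.null(x$f_c) || is.na(x$f_c)) "" else sprintf(" (f_c %.4g /mm)", x$f_c),
              x$edge_blur_sigma,
              if (is.null(x$blotch)) "none" else
                sprintf("%.3g /mm^2 x %.3g HU x %.3g mm", x$blotch$density,
                        x$blotch$amplitude, x$blotch$width)))
  invisible(x)
}

#' Noise magnitude implied by a model at given scan conditions
#'
#' @param model a [noise_model()].
#' @param dose dose (CTDI_vol), mGy.
#' @param thickness slice thickness, mm.
#' @return Noise SD, HU.
#' @export
noise_sigma <- function(model, dose, thickness = model$thickness_ref) {
  if (!is.finite(dose) || dose <= 0) stop("dose must be > 0")
  if (!is.finite(thickness) || thickness <= 0) stop("thickness must be > 0")
  model$sigma_ref * (dose / model$d_ref)^model$dose_exponent *
    (thickness / model$thickness_ref)^model$thickness_exponent
}

#' Synthesize a colored Gaussian noise field
#'
#' Spectrally weights complex white noise with the square root of the target
#' radial NPS shape, inverse-transforms, and rescales so the sample standard
#' deviation equals the dose- and thickness-scaled target
#' (see [noise_sigma()]). The DC component is zeroed, so the field is exactly
#' zero-mean.
#'
#' @param shape integer `c(rows, cols)`; at least 64 x 64.
#' @param spacing pixel spacing, mm.
#' @param model a [noise_model()].
#' @param dose dose, mGy.
#' @param thickness slice thickness, mm.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return A `rows x cols` numeric matrix of HU deviations.
#' @export
synthesize_noise <- function(shape, spacing, model, dose,
                             thickness = model$thickness_ref, seed = NULL) {
  stopifnot(length(shape) == 2)
  if (any(shape < 64)) stop("noise field must be at least 64 x 64")
  sigma <- noise_sigma(model, dose, thickness)
  if (!is.finite(sigma) || sigma <= 0) stop("target noise SD must be > 0")
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fu <- fft_freqs(nr, spacing)
  fv <- fft_freqs(nc, spacing)
  r <- sqrt(outer(fu^2, fv^2, "+"))
  h <- sqrt(nps_shape_value(r, model$nps_family, model$f_c))
  dim(h) <- c(nr, nc)
  h[1, 1] <- 0  # zero mean
  x <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / (nr * nc)
  x <- x - mean(x)
  x * (sigma / stats::sd(x))
}

# Sparse zero-mean blotch field: Poisson-count Gaussian bumps with random
# sign, emulating the patchy low-frequency artifacts of iterative
# reconstruction. Draws from the current RNG stream.
blotch_field <- function(shape, spacing, blotch, scale = 1) {
  nr <- shape[1]; nc <- shape[2]
  field <- matrix(0, nr, nc)
  area <- nr * nc * spacing^2
  n <- stats::rpois(1, blotch$density * area)
  if (n == 0) return(field)
  cx <- stats::runif(n, 0.5, nc + 0.5)
  cy <- stats::runif(n, 0.5, nr + 0.5)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  amp <- blotch$amplitude * scale
  w_px <- blotch$width / spacing
  half <- ceiling(4 * w_px)
  for (k in seq_len(n)) {
    rows <- max(1, floor(cy[k] - half)):min(nr, ceiling(cy[k] + half))
    cols <- max(1, floor(cx[k] - half)):min(nc, ceiling(cx[k] + half))
    d2 <- outer((rows - cy[k])^2, (cols - cx[k])^2, "+")
    field[rows, cols] <- field[rows, cols] +
      sgn[k] * amp * exp(-d2 / (2 * w_px^2))
  }
  field
}

#' Study-condition noise models
#'
#' The seven reconstruction-algorithm emulations used throughout the package
#' examples: filtered back projection (FBP), three hybrid iterative
#' reconstruction blends (IR50/IR70/IR90) and three deep-learning
#' reconstruction strengths (DLL/DLM/DLH). Noise magnitudes encode the 33%,
#' 46% and 60% reductions of the DLR strengths relative to a 10 HU FBP
#' baseline at 25 mGy / 2.5 mm (hybrid IR levels parallel them); NPS average
#' frequencies are FBP-like ~0.31 down to IR-like ~0.19 cycles/mm; hybrid IR
#' carries blotch artifacts and progressively stronger edge blur.
#'
#' @param spacing pixel spacing (mm) used to calibrate the spectral shapes.
#' @param sigma_fbp FBP noise SD (HU) at 25 mGy / 2.5 mm.
#' @return Named list of seven [noise_model()] objects.
#' @export
ctiq_study_models <- function(spacing = 0.6854, sigma_fbp = 10) {
  mk <- function(label, rel_noise, favg, family, blur, blotch = NULL)
    noise_model(label, sigma_ref = sigma_fbp * rel_noise, d_ref = 25,
                nps_family = family, target_favg = favg, spacing = spacing,
                edge_blur_sigma = blur, blotch = blotch)
  bl <- function(amp) list(density = 2e-4, amplitude = amp, width = 1.3)
  list(
    FBP  = mk("FBP",  1.00, 0.31, "fbp-like", 0.55),
    IR50 = mk("IR50", 0.67, 0.27, "ir-like",  0.72, bl(27)),
    IR70 = mk("IR70", 0.54, 0.23, "ir-like",  0.79, bl(30)),
    IR90 = mk("IR90", 0.40, 0.19, "ir-like",  0.87, bl(37)),
    DLL  = mk("DLL",  0.67, 0.30, "fbp-like", 0.65),
    DLM  = mk("DLM",  0.54, 0.30, "fbp-like", 0.69),
    DLH  = mk("DLH",  0.40, 0.29, "fbp-like", 0.75)
  )
}
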