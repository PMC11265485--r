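# Noise-dose modelling: log-log regression per algorithm, equivalent dose,
# and dose-reduction estimates with delta-method confidence intervals.

#' Fit the noise-dose power law
#'
#' Ordinary least squares of `ln(noise)` on `ln(dose)`; under quantum-noise
#' scaling the slope is -1/2. Observations are typically per-scan mean noise
#' values (repeats x dose levels).
#'
#' @param dose doses, mGy (> 0).
#' @param noise noise SDs, HU (> 0); same length.
#' @param label algorithm label carried through to reports.
#' @return An object of class `ctiq_dose_fit` with intercept `a`, slope `b`,
#'   the 2x2 coefficient covariance, `n` and the residual variance.
#' @export
fit_noise_dose <- function(dose, noise, label = "algorithm") {
  if (length(dose) != length(noise)) stop("dose and noise length mismatch")
  if (length(dose) < 3) stop("need at least 3 (dose, noise) points")
  if (any(!is.finite(dose)) || any(dose <= 0)) stop("doses must be > 0")
  if (any(!is.finite(noise)) || any(noise <= 0)) stop("noise must be > 0")
  fit <- stats::lm(log(noise) ~ log(dose))
  cv <- stats::vcov(fit)
  structure(list(algorithm = label,
                 a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 cov = unname(cv), n = length(dose),
                 sigma2 = summary(fit)$sigma^2),
            class = "ctiq_dose_fit")
}

#' @export
print.ctiq_dose_fit <- function(x, ...) {
  cat(sprintf("ctiq dose fit '%s': ln(noise) = %.4g %+.4g ln(dose), n = %d, residual SD %.3g\n",
              x$algorithm, x$a, x$b, x$n, sqrt(x$sigma2)))
  invisible(x)
}

#' Dose at which a test algorithm matches the reference noise
#'
#' Solves `a_t + b_t ln(D) = a_r + b_r ln(D_ref)` for `D`: the dose at which
#' the test algorithm's noise equals the reference algorithm's noise at
#' `D_ref`.
#'
#' @param fit_test,fit_ref [fit_noise_dose()] objects.
#' @param d_ref reference dose, mGy.
#' @return Equivalent dose, mGy.
#' @export
equivalent_dose <- function(fit_test, fit_ref, d_ref) {
  if (fit_test$b == 0) {
    if (abs(fit_test$a - (fit_ref$a + fit_ref$b * log(d_ref))) > 1e-12)
      stop("test noise is dose-independent and never matches the reference")
    return(d_ref)
  }
  exp((fit_ref$a + fit_ref$b * log(d_ref) - fit_test$a) / fit_test$b)
}

#' Dose-reduction potential with a delta-method confidence interval
#'
#' The saving `delta = D_ref - D_equiv` (and `percent = 100 delta / D_ref`)
#' a test algorithm affords while maintaining the reference algorithm's
#' noise at `D_ref`. The variance of `delta` is propagated by the delta
#' method through all four regression coefficients, using the
#' block-diagonal covariance of the two independent fits; the 95% interval
#' is `delta +/- 1.96 SE` and the p-value is the two-sided Wald test of
#' `delta = 0`. Set `fixed_reference = TRUE` to treat the reference fit as
#' known (sensitivity mode).
#'
#' @param fit_test,fit_ref [fit_noise_dose()] objects.
#' @param d_ref reference dose, mGy.
#' @param fixed_reference ignore the reference fit's uncertainty.
#' @param level confidence level (normal quantile).
#' @return An object of class `ctiq_dose_reduction`.
#' @export
dose_reduction <- function(fit_test, fit_ref, d_ref, fixed_reference = FALSE,
                           level = 0.95) {
  d_eq <- equivalent_dose(fit_test, fit_ref, d_ref)
  delta <- d_ref - d_eq
  bt <- fit_test$b
  l <- log(d_eq)
  # gradient of delta w.r.t. (a_t, b_t, a_r, b_r)
  grad <- c(d_eq / bt, d_eq * l / bt, -d_eq / bt, -d_eq * log(d_ref) / bt)
  cov4 <- matrix(0, 4, 4)
  cov4[1:2, 1:2] <- fit_test$cov
  if (!fixed_reference) cov4[3:4, 3:4] <- fit_ref$cov
  se <- sqrt(drop(t(grad) %*% cov4 %*% grad))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) ifelse(delta == 0, 1, 0) else
    2 * stats::pnorm(-abs(delta) / se)
  structure(list(test = fit_test$algorithm, reference = fit_ref$algorithm,
                 d_ref = d_ref, d_equiv = d_eq, delta = delta,
                 percent = 100 * delta / d_ref,
                 se = se, ci95 = c(delta - z * se, delta + z * se),
                 p = p, fixed_reference = fixed_reference),
            class = "ctiq_dose_reduction")
}

#' @export
print.ctiq_dose_reduction <- function(x, ...) {
  cat(sprintf("dose reduction of '%s' vs '%s' at %g mGy:\n", x$test,
              x$reference, x$d_ref))
  cat(sprintf("  equivalent dose %.3g mGy, saving %.3g mGy (%.0f%%), 95%% CI %.3g-%.3g mGy, p %s\n",
              x$d_equiv, x$delta, round(x$percent), x$ci95[1], x$ci95[2],
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Monte-Carlo coverage of the delta-method interval
#'
#' Simulates the noise-dose design from a known truth (lognormal noise about
#' per-arm power laws), recomputes the dose-reduction CI each time, and
#' returns the fraction of intervals covering the true saving.
#'
#' @param truth list with `a_test`, `b_test`, `a_ref`, `b_ref` (log-scale
#'   power-law coefficients), `tau` (SD of the log-noise scatter), `doses`
#'   and `repeats`.
#' @param d_ref reference dose, mGy.
#' @param n_sims number of simulations (>= 200).
#' @param seed integer seed.
#' @return `list(coverage, true_delta, n_sims)`.
#' @export
ci_coverage_check <- function(truth, d_ref = 25, n_sims = 500, seed = 1) {
  if (n_sims < 200) stop("n_sims must be >= 200")
  set.seed(seed)
  true_fit <- function(a, b) structure(list(algorithm = "truth", a = a, b = b,
                                            cov = matrix(0, 2, 2)),
                                       class = "ctiq_dose_fit")
  true_delta <- d_ref - equivalent_dose(true_fit(truth$a_test, truth$b_test),
                                        true_fit(truth$a_ref, truth$b_ref),
                                        d_ref)
  doses <- rep(truth$doses, each = truth$repeats)
  hits <- 0L
  for (s in seq_len(n_sims)) {
    noise_t <- exp(truth$a_test + truth$b_test * log(doses) +
                     stats::rnorm(length(doses), 0, truth$tau))
    noise_r <- exp(truth$a_ref + truth$b_ref * log(doses) +
                     stats::rnorm(length(doses), 0, truth$tau))
    dr <- dose_reduction(fit_noise_dose(doses, noise_t, "test"),
                         fit_noise_dose(doses, noise_r, "ref"), d_ref)
    if (dr$ci95[1] <= true_delta && true_delta <= dr$ci95[2])
      hits <- hits + 1L
  }
  list(coverage = hits / n_sims, true_delta = true_delta, n_sims = n_sims)
}
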