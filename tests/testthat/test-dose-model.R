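test_that("an exact power law is recovered with zero residuals", {
  d <- c(5, 10, 15, 20, 25)
  noise <- 10 * (d / 25)^(-0.5)
  fit <- suppressWarnings(fit_noise_dose(d, noise, "exact"))
  expect_equal(fit$b, -0.5, tolerance = 1e-10)
  expect_equal(fit$a, log(10) + 0.5 * log(25), tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-20)
  # dose-independent noise gives a flat slope
  set.seed(8)
  flat <- suppressWarnings(fit_noise_dose(d, rep(10, 5) * exp(rnorm(5, 0, 1e-4)),
                                          "flat"))
  expect_equal(flat$b, 0, tolerance = 1e-3)
  expect_error(fit_noise_dose(c(5, 10), c(1, 2)), "at least 3")
  expect_error(fit_noise_dose(d, -noise), "noise")
  expect_error(fit_noise_dose(-d, noise), "dose")
})

test_that("duplicating every observation keeps the fit and shrinks the covariance as OLS dictates", {
  set.seed(17)
  d <- rep(c(5, 10, 15, 20, 25), each = 3)
  noise <- 10 * (d / 25)^(-0.5) * exp(rnorm(length(d), 0, 0.05))
  f1 <- fit_noise_dose(d, noise, "x")
  f2 <- fit_noise_dose(c(d, d), c(noise, noise), "x")
  expect_equal(f2$a, f1$a, tolerance = 1e-12)
  expect_equal(f2$b, f1$b, tolerance = 1e-12)
  # closed-form OLS oracle: vcov = sigma2 * (X'X)^-1 with RSS and df by hand
  X <- cbind(1, log(d))
  res <- log(noise) - X %*% c(f1$a, f1$b)
  n <- length(d)
  expected_cov2 <- (2 * sum(res^2) / (2 * n - 2)) * solve(2 * crossprod(X))
  expect_equal(f2$cov, unname(expected_cov2), tolerance = 1e-10)
  # asymptotically the covariance halves: (n-2)/(2n-2) of a half at n = 15
  expect_equal(f2$cov[2, 2] / f1$cov[2, 2], 0.5, tolerance = 0.08)
})

test_that("equivalent dose obeys the matched-slope closed form", {
  d <- c(5, 10, 15, 20, 25)
  ref_noise <- 10 * (d / 25)^(-0.5)
  fit_ref <- suppressWarnings(fit_noise_dose(d, ref_noise, "ref"))
  expect_equal(equivalent_dose(fit_ref, fit_ref, 25), 25)
  for (r in c(0.4, 0.6, 0.67)) {
    fit_r <- suppressWarnings(fit_noise_dose(d, r * ref_noise, "r"))
    expect_equal(equivalent_dose(fit_r, fit_ref, 25), r^2 * 25,
                 tolerance = 1e-8)
  }
  # r = 0.6 at 25 mGy: equivalent dose 9, saving 16 mGy, 64%
  fit06 <- suppressWarnings(fit_noise_dose(d, 0.6 * ref_noise, "r06"))
  dr <- dose_reduction(fit06, fit_ref, 25)
  expect_equal(dr$d_equiv, 9, tolerance = 1e-8)
  expect_equal(dr$delta, 16, tolerance = 1e-8)
  expect_equal(dr$percent, 64, tolerance = 1e-8)
  # percent is exactly 100 * delta / d_ref
  expect_identical(dr$percent, 100 * dr$delta / dr$d_ref)
})

test_that("a printed-style saving of 18.4 mGy at a 25 mGy reference is 74 percent", {
  d <- c(5, 10, 15, 20, 25)
  ref_noise <- 10 * (d / 25)^(-0.5)
  fit_ref <- suppressWarnings(fit_noise_dose(d, ref_noise, "ref"))
  r <- sqrt((25 - 18.4) / 25)  # noise ratio implying a 6.6 mGy equivalent dose
  fit_t <- suppressWarnings(fit_noise_dose(d, r * ref_noise, "test"))
  dr <- dose_reduction(fit_t, fit_ref, 25)
  expect_equal(dr$delta, 18.4, tolerance = 1e-8)
  expect_equal(round(dr$percent), 74)
  expect_true(dr$ci95[1] <= dr$delta && dr$delta <= dr$ci95[2])
  # identical arms: no saving, p = 1
  same <- dose_reduction(fit_ref, fit_ref, 25)
  expect_equal(same$delta, 0, tolerance = 1e-12)
  expect_equal(same$percent, 0, tolerance = 1e-12)
})

test_that("percent saving is invariant to a common rescaling of both arms' noise", {
  set.seed(23)
  d <- rep(c(5, 10, 15, 20, 25), each = 3)
  nt <- 6 * (d / 25)^(-0.45) * exp(rnorm(length(d), 0, 0.04))
  nr <- 10 * (d / 25)^(-0.52) * exp(rnorm(length(d), 0, 0.04))
  dr1 <- dose_reduction(fit_noise_dose(d, nt, "t"), fit_noise_dose(d, nr, "r"), 25)
  dr2 <- dose_reduction(fit_noise_dose(d, 3.7 * nt, "t"),
                        fit_noise_dose(d, 3.7 * nr, "r"), 25)
  expect_equal(dr2$percent, dr1$percent, tolerance = 1e-10)
  expect_equal(dr2$se, dr1$se, tolerance = 1e-10)
})

test_that("the delta-method interval agrees with a parametric bootstrap", {
  set.seed(41)
  d <- rep(c(5, 10, 15, 20, 25), each = 3)
  tau <- 0.05
  nt <- 6.7 * (d / 25)^(-0.5) * exp(rnorm(length(d), 0, tau))
  nr <- 10 * (d / 25)^(-0.5) * exp(rnorm(length(d), 0, tau))
  ft <- fit_noise_dose(d, nt, "t")
  fr <- fit_noise_dose(d, nr, "r")
  dr <- dose_reduction(ft, fr, 25)
  # bootstrap oracle: resample lognormal noise from each fitted model
  boot <- vapply(1:2000, function(i) {
    bt <- exp(ft$a + ft$b * log(d) + rnorm(length(d), 0, sqrt(ft$sigma2)))
    br <- exp(fr$a + fr$b * log(d) + rnorm(length(d), 0, sqrt(fr$sigma2)))
    dose_reduction(fit_noise_dose(d, bt, "t"),
                   fit_noise_dose(d, br, "r"), 25)$delta
  }, numeric(1))
  ci_boot <- quantile(boot, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(ci_boot[1] - dr$ci95[1]), 0.15 * dr$se)
  expect_lt(abs(ci_boot[2] - dr$ci95[2]), 0.15 * dr$se)
})

test_that("delta-method coverage is nominal, also under a misspecified dose exponent", {
  truth <- list(a_test = log(6.7) + 0.5 * log(25), b_test = -0.5,
                a_ref = log(10) + 0.5 * log(25), b_ref = -0.5,
                tau = 0.05, doses = c(5, 10, 15, 20, 25), repeats = 3)
  cov1 <- ci_coverage_check(truth, d_ref = 25, n_sims = 500, seed = 3)
  expect_gte(cov1$coverage, 0.92)
  expect_lte(cov1$coverage, 0.98)
  # slope is fitted, not imposed: a -0.3 exponent truth stays covered
  truth2 <- truth
  truth2$b_test <- -0.3; truth2$b_ref <- -0.3
  cov2 <- ci_coverage_check(truth2, d_ref = 25, n_sims = 500, seed = 4)
  expect_gte(cov2$coverage, 0.90)
  expect_lte(cov2$coverage, 0.98)
  expect_error(ci_coverage_check(truth, n_sims = 50), ">= 200")
})
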