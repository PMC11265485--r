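# Shared fixtures: a scaled-down phantom for fast tests (same materials and
# lesion as the full layout, smaller body and inserts) and noise-model
# shortcuts. Everything is generated in code at test time.

small_layout <- function() {
  ctiq_layout(grid_size = c(192L, 192L),
              body_semiaxes = c(60, 45),
              insert_center = c(-32, 0),
              insert_diameter = 40,
              lowc_center = c(32, 0))
}

# plain colored-noise model without artifacts or blur
nm <- function(sigma = 10, favg = 0.30, family = "fbp-like", label = "test",
               spacing = 0.6854, ...) {
  noise_model(label, sigma_ref = sigma, d_ref = 25, nps_family = family,
              target_favg = if (family == "white") NULL else favg,
              spacing = spacing, ...)
}

white_model <- function(sigma = 10, label = "white")
  noise_model(label, sigma_ref = sigma, d_ref = 25, nps_family = "white")

# analytic profile of a disk (radius R, height `contrast` on `base`)
# convolved with an isotropic Gaussian of SD sigma, evaluated at radius r.
# Independent 1D oracle via the Rician/Marcum integral with the scaled
# Bessel function for numerical stability.
blurred_disk_profile <- function(r, R, sigma, contrast, base) {
  vapply(r, function(ri) {
    f <- function(s) s / sigma^2 *
      besselI(ri * s / sigma^2, 0, expon.scaled = TRUE) *
      exp(-(ri - s)^2 / (2 * sigma^2))
    base + contrast * stats::integrate(f, 0, R, rel.tol = 1e-9)$value
  }, numeric(1))
}
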