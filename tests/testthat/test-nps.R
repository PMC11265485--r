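test_that("the 2D NPS of white noise is flat at the analytic level", {
  sp <- 0.6854
  set.seed(21)
  rois <- lapply(1:20, function(i) matrix(rnorm(64 * 64, sd = 10), 64, 64))
  n2 <- nps_2d(rois, sp, detrend = "mean")
  expect_equal(mean(n2$nps2d[-1]), sp^2 * 100, tolerance = 0.03)
  expect_equal(n2$nps2d[1, 1], 0)  # DC bin is zero after mean subtraction
  ra <- radial_average(n2)
  # flat spectrum stays flat after radial averaging
  expect_lt(sd(ra$nps[-1]) / mean(ra$nps[-1]), 0.15)
  # and its average frequency is Nyquist/2 up to binning
  expect_equal(f_avg(ra$freq, ra$nps), 1 / (4 * sp),
               tolerance = 0.03)
})

test_that("degenerate and malformed ROI sets are rejected or give zero spectra", {
  sp <- 0.6854
  const <- lapply(1:4, function(i) matrix(5, 64, 64))
  n2 <- nps_2d(const, sp, detrend = "mean")
  expect_true(all(n2$nps2d == 0))
  expect_error(nps_2d(const[1:3], sp), "at least 4")
  bad <- c(const[1:3], list(matrix(0, 32, 32)))
  expect_error(nps_2d(bad, sp), "identical size")
  expect_error(nps_2d(c(const[1:3], list(matrix(0, 64, 32))), sp),
               "identical size")
})

test_that("radial averaging recovers a radially symmetric spectrum", {
  sp <- 0.6854
  w <- 64
  fr <- ctiq:::fft_freqs(w, sp)
  r <- sqrt(outer(fr^2, fr^2, "+"))
  g <- exp(-r / 0.3)
  ra <- radial_average(g, spacing = sp)
  expect_true(all(diff(ra$freq) > 0))
  expect_lte(max(ra$freq), 1 / (2 * sp) + 1e-9)
  expect_equal(ra$nps, exp(-ra$freq / 0.3), tolerance = 0.05)
})

test_that("Parseval holds: total power tracks the detrended pixel variance", {
  lay <- small_layout()
  st <- simulate_scan(lay, nm(10, favg = 0.28), 25, 2.5, 20, seed = 14)
  res <- estimate_nps(st, lay, detrend = "poly1")
  # variance of the central-insert noise at these conditions is ~100 HU^2
  expect_equal(res$total_power, 100, tolerance = 0.15)
  # normalized curve integrates to one
  df <- res$freq_axis[2] - res$freq_axis[1]
  expect_equal(sum(res$nnps1d) * df, 1, tolerance = 1e-6)
})

test_that("normalization and cross-scan averaging behave as an arithmetic mean", {
  c1 <- data.frame(freq = seq(0, 0.7, by = 0.05), nps = runif(15, 1, 2))
  res1 <- normalize_and_average(list(c1))
  expect_equal(res1$nps1d, c1$nps)  # single scan: identity
  # scaling every input by a constant leaves the normalized curve unchanged
  c2 <- c1; c2$nps <- 7.3 * c1$nps
  res2 <- normalize_and_average(list(c2))
  expect_equal(res2$nnps1d, res1$nnps1d)
  expect_equal(res2$f_avg, res1$f_avg)
  mismatch <- c1; mismatch$freq <- mismatch$freq + 0.01
  expect_error(normalize_and_average(list(c1, mismatch)), "frequency axes")
  zero <- c1; zero$nps <- 0
  expect_error(normalize_and_average(list(zero)), "zero total power")
})

test_that("averaging repeat scans reduces the spectral variance", {
  sp <- 0.6854
  m <- nm(10, favg = 0.30)
  curve_of <- function(seed, n_fields = 4) {
    fields <- lapply(seq_len(n_fields), function(i)
      synthesize_noise(c(64, 64), sp, m, 25, seed = seed * 100 + i))
    radial_average(nps_2d(fields, sp, detrend = "mean"))
  }
  singles <- lapply(1:12, curve_of)
  mid <- 15  # a mid-frequency bin
  single_vals <- vapply(singles, function(c2) c2$nps[mid], numeric(1))
  triple_vals <- vapply(list(1:3, 4:6, 7:9, 10:12), function(idx)
    normalize_and_average(singles[idx])$nps1d[mid], numeric(1))
  expect_lt(var(triple_vals), var(single_vals))
})

test_that("f_avg is the power-weighted mean frequency and orders textures correctly", {
  freq <- seq(0, 0.7, by = 0.05)
  one_bin <- rep(0, length(freq)); one_bin[8] <- 3
  expect_equal(f_avg(freq, one_bin), freq[8])
  expect_error(f_avg(freq, rep(0, length(freq))), "all-zero")
  expect_error(f_avg(freq, one_bin[-1]), "mismatch")
  # measured f_avg rises monotonically with the shape cutoff f_c
  sp <- 0.6854
  measured <- vapply(c(0.2, 0.3, 0.45), function(fc) {
    m <- noise_model("x", 10, nps_family = "fbp-like", f_c = fc)
    fields <- lapply(1:4, function(i)
      synthesize_noise(c(96, 96), sp, m, 25, seed = fc * 1000 + i))
    ra <- radial_average(nps_2d(fields, sp, detrend = "mean"))
    f_avg(ra$freq, ra$nps)
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("doubling the ROI count roughly halves the variance of a spectral bin", {
  sp <- 0.6854
  m <- nm(10, favg = 0.30)
  bins <- c(8, 10, 12, 14, 16)
  bin_vals <- function(n_rois, seed) {
    fields <- lapply(seq_len(n_rois), function(i)
      synthesize_noise(c(64, 64), sp, m, 25, seed = seed * 1000 + i))
    radial_average(nps_2d(fields, sp, detrend = "mean"))$nps[bins]
  }
  v8 <- apply(vapply(1:200, function(s) bin_vals(8, s),
                     numeric(length(bins))), 1, var)
  v16 <- apply(vapply(201:400, function(s) bin_vals(16, s),
                      numeric(length(bins))), 1, var)
  ratio <- sum(v8) / sum(v16)
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})

test_that("the radial profile of synthesized noise matches the generator's target shape", {
  sp <- 0.6854
  m <- nm(10, favg = 0.30)
  fields <- lapply(1:16, function(i)
    synthesize_noise(c(128, 128), sp, m, 25, seed = 5000 + i))
  n2 <- nps_2d(fields, sp, detrend = "mean")
  ra <- radial_average(n2)
  # compare normalized measured curve with the normalized analytic shape on
  # bins excluding DC (zeroed by the generator)
  sel <- ra$freq > 0
  target <- ctiq:::nps_shape_value(ra$freq[sel], "fbp-like", m$f_c)
  meas <- ra$nps[sel] / sum(ra$nps[sel])
  target <- target / sum(target)
  rms <- sqrt(mean((meas - target)^2)) / mean(target)
  expect_lt(rms, 0.10)
})
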