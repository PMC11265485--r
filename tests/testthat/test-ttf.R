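test_that("the lesion centre is found at subpixel precision and is rotation invariant", {
  lay <- ctiq_layout()
  sp <- lay$pixel_spacing
  img <- gaussian_blur(ctiq:::render_slice(lay, TRUE), 0.6, sp)
  # continuous-truth centre in pixel coordinates
  truth <- c(lay$lowc_center[2] / sp + (lay$grid_size[1] + 1) / 2,
             lay$lowc_center[1] / sp + (lay$grid_size[2] + 1) / 2)
  ctr <- find_center(img, round(truth), lay$lesion_diameter / 2 / sp)
  expect_lt(sqrt(sum((ctr - truth)^2)), 0.2)
  # rotate the image 90 degrees: pixel (r, c) maps to (c, n + 1 - r), and so
  # must the centroid
  n <- nrow(img)
  rot <- t(img)[, rev(seq_len(n))]
  ctr_rot <- find_center(rot, round(c(truth[2], n + 1 - truth[1])),
                         lay$lesion_diameter / 2 / sp)
  expect_equal(unname(ctr_rot), unname(c(ctr[2], n + 1 - ctr[1])),
               tolerance = 1e-6)
  # no lesion present -> rejection
  plain <- ctiq:::render_slice(lay, FALSE)
  expect_error(find_center(plain, round(truth), 10), "contrast below 5 HU")
})

test_that("the radial ESF of the unblurred lesion steps at the lesion radius", {
  lay <- ctiq_layout()
  st <- render_phantom(lay, 10)
  ctr <- find_center(st$voxels[, , 5], mm_to_px(lay, lay$lowc_center),
                     lay$lesion_diameter / 2 / lay$pixel_spacing)
  esf <- radial_esf(st, ctr, r_max = 13.5)
  # inside the rod: 80 HU; outside: 55 HU; transition within one bin of 7.5 mm
  expect_equal(esf$esf[esf$r < 6], rep(80, sum(esf$r < 6)), tolerance = 1e-9)
  expect_equal(esf$esf[esf$r > 9], rep(55, sum(esf$r > 9)), tolerance = 1e-9)
  mid <- (80 + 55) / 2
  cross <- esf$r[which(esf$esf < mid)[1]]
  expect_lt(abs(cross - 7.5), 2 * 0.25 * lay$pixel_spacing)
})

test_that("the blurred-lesion ESF matches the analytic blurred-disk profile", {
  lay <- ctiq_layout()
  sigma <- 0.8
  img <- gaussian_blur(ctiq:::render_slice(lay, TRUE), sigma,
                       lay$pixel_spacing)
  st <- image_stack(array(rep(img, 10), c(dim(img), 10)), lay$pixel_spacing,
                    2.5)
  ctr <- find_center(img, mm_to_px(lay, lay$lowc_center),
                     lay$lesion_diameter / 2 / lay$pixel_spacing)
  esf <- radial_esf(st, ctr, r_max = 13.5)
  oracle <- blurred_disk_profile(esf$r, R = 7.5, sigma = sigma,
                                 contrast = 25, base = 55)
  expect_lt(sqrt(mean((esf$esf - oracle)^2)), 0.5)
})

test_that("a pure noise field yields a flat ESF", {
  lay <- small_layout()
  m <- nm(10)
  fields <- vapply(1:10, function(i)
    synthesize_noise(c(192, 192), lay$pixel_spacing, m, 25, seed = 300 + i) + 50,
    matrix(0, 192, 192))
  st <- image_stack(fields, lay$pixel_spacing, 2.5)
  esf <- radial_esf(st, c(96.27, 96.61), r_max = 13.5)
  # every bin within a few standard errors of the common mean
  se <- 10 / sqrt(pmax(esf$n, 1))
  expect_true(all(abs(esf$esf - 50) < 6 * pmax(se, 0.5)))
})

test_that("f50 recovers the Gaussian closed form and scales inversely with blur", {
  lay <- ctiq_layout()
  f50_of <- function(sigma) {
    img <- gaussian_blur(ctiq:::render_slice(lay, TRUE), sigma,
                         lay$pixel_spacing)
    st <- image_stack(array(rep(img, 10), c(dim(img), 10)),
                      lay$pixel_spacing, 2.5)
    ctr <- find_center(img, mm_to_px(lay, lay$lowc_center),
                       lay$lesion_diameter / 2 / lay$pixel_spacing)
    esf_to_ttf(radial_esf(st, ctr, r_max = 13.5))$f50
  }
  closed_form <- function(sigma) sqrt(log(2) / (2 * pi^2 * sigma^2))
  f50_055 <- f50_of(0.55)
  f50_075 <- f50_of(0.75)
  expect_equal(f50_055, closed_form(0.55), tolerance = 0.05)
  expect_equal(f50_075, closed_form(0.75), tolerance = 0.05)
  # doubling the blur halves f50
  f50_06 <- f50_of(0.6); f50_12 <- f50_of(1.2)
  expect_equal(f50_12 / f50_06, 0.5, tolerance = 0.05)
  # monotone ordering across blur levels (sharper algorithms score higher)
  f50_03 <- f50_of(0.3)
  expect_true(f50_03 > f50_06 && f50_06 > f50_12)
})

test_that("f50 is invariant to lesion polarity and HU offset", {
  lay_hyper <- ctiq_layout()
  lay_hypo <- ctiq_layout(lesion_hu = 30)  # hypo-attenuating, same |contrast|
  f50_of_layout <- function(lay, offset = 0) {
    img <- gaussian_blur(ctiq:::render_slice(lay, TRUE), 0.7,
                         lay$pixel_spacing) + offset
    st <- image_stack(array(rep(img, 10), c(dim(img), 10)),
                      lay$pixel_spacing, 2.5)
    ctr <- find_center(img, mm_to_px(lay, lay$lowc_center),
                       lay$lesion_diameter / 2 / lay$pixel_spacing)
    esf_to_ttf(radial_esf(st, ctr, r_max = 13.5))$f50
  }
  f_hyper <- f50_of_layout(lay_hyper)
  f_hypo <- f50_of_layout(lay_hypo)
  expect_equal(f_hypo, f_hyper, tolerance = 0.02)
  expect_equal(f50_of_layout(lay_hyper, offset = 100), f_hyper,
               tolerance = 1e-9)
})

test_that("an ideal step edge bounds blurred edges from above and saturates the band", {
  r <- seq(0.1, 13.5, by = 0.17)
  esf <- data.frame(r = r, esf = ifelse(r < 7.5, 80, 55))
  tt <- esf_to_ttf(esf)
  # the step reads as sharper than anything measurable at this pixel pitch
  expect_gt(tt$f50, 1 / (2 * 0.6854))
  # and bounds the blurred profile at every frequency in the physical band
  oracle <- blurred_disk_profile(r, 7.5, 1.0, 25, 55)
  tt_blur <- esf_to_ttf(data.frame(r = r, esf = oracle))
  band <- tt$freq_axis < 0.8
  expect_true(all(tt$ttf[band] >= tt_blur$ttf[band] - 0.02))
})

test_that("a curve that never falls below half maximum reports f50 as not reached", {
  freq <- seq(0, 1, by = 0.01)
  mk <- function(level) structure(
    list(freq_axis = freq, ttf = rep(level, length(freq)), f50 = NA_real_,
         f50_reached = FALSE, contrast = 25, n_slices = 10),
    class = "ctiq_ttf")
  avg <- ttf_average(list(mk(0.9), mk(0.8)))
  expect_true(is.na(avg$f50))
  expect_false(avg$f50_reached)
})

test_that("TTF averaging is pointwise, bounded and recomputes f50", {
  r <- seq(0.1, 13.5, by = 0.17)
  mk <- function(sigma) esf_to_ttf(data.frame(
    r = r, esf = blurred_disk_profile(r, 7.5, sigma, 25, 55)))
  a <- mk(0.6); b <- mk(1.0)
  same <- ttf_average(list(a, a))
  expect_equal(same$ttf, a$ttf)
  expect_equal(as.numeric(same$f50), as.numeric(a$f50), tolerance = 1e-9)
  avg <- ttf_average(list(a, b))
  expect_true(all(avg$ttf <= pmax(a$ttf, b$ttf) + 1e-12))
  expect_true(all(avg$ttf >= pmin(a$ttf, b$ttf) - 1e-12))
  expect_true(as.numeric(avg$f50) < as.numeric(a$f50) &&
                as.numeric(avg$f50) > as.numeric(b$f50))
  short <- a; short$freq_axis <- a$freq_axis[-1]; short$ttf <- a$ttf[-1]
  expect_error(ttf_average(list(a, short)), "frequency axes")
})

test_that("f50 stays near the noiseless value under measurement noise", {
  lay <- small_layout()
  m <- nm(6, favg = 0.30, label = "noisy", edge_blur_sigma = 0.7)
  noiseless <- sqrt(log(2) / (2 * pi^2 * 0.7^2))
  f50s <- vapply(1:10, function(i) {
    st <- simulate_scan(lay, m, 25, 2.5, 10, seed = 400 + i)
    as.numeric(estimate_ttf(st, lay)$f50)
  }, numeric(1))
  expect_equal(mean(f50s), noiseless, tolerance = 0.10)
})
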