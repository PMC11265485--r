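# Noiseless phantom rendering and structural blurring.

# one axial slice of the phantom; with_lesion toggles the lesion rod
render_slice <- function(layout, with_lesion) {
  nr <- layout$grid_size[1]; nc <- layout$grid_size[2]
  sp <- layout$pixel_spacing
  x <- axis_mm(nc, sp)                 # along columns
  y <- axis_mm(nr, sp)                 # along rows
  xm <- matrix(x, nr, nc, byrow = TRUE)
  ym <- matrix(y, nr, nc)
  img <- matrix(layout$air_hu, nr, nc)
  inside <- (xm / layout$body_semiaxes[1])^2 +
    (ym / layout$body_semiaxes[2])^2 <= 1
  img[inside] <- layout$background_hu
  r2 <- (layout$insert_diameter / 2)^2
  img[(xm - layout$insert_center[1])^2 + (ym - layout$insert_center[2])^2 <= r2] <-
    layout$insert_hu
  in_lowc <- (xm - layout$lowc_center[1])^2 + (ym - layout$lowc_center[2])^2 <= r2
  img[in_lowc] <- layout$lowc_hu
  if (with_lesion) {
    rl2 <- (layout$lesion_diameter / 2)^2
    img[(xm - layout$lowc_center[1])^2 + (ym - layout$lowc_center[2])^2 <= rl2] <-
      layout$lesion_hu
  }
  img
}

# slices carrying the lesion rod: |z| within half the axial extent
lesion_slices <- function(layout, n, thickness)
  which(abs(slice_z(n, thickness)) <= layout$lesion_extent / 2)

#' Render the noiseless phantom
#'
#' Assigns to every voxel the CT number of the region containing its pixel
#' centre: air outside the body outline, the body background, the two insert
#' materials, and the lesion rod on the slices its axial extent covers
#' (centred in the stack).
#'
#' @param layout a [ctiq_layout()].
#' @param n_slices number of axial slices.
#' @param slice_thickness slice thickness, mm.
#' @return A noiseless [image_stack()] (`dose_ctdi = NA`).
#' @export
render_phantom <- function(layout, n_slices, slice_thickness = 2.5) {
  stopifnot(inherits(layout, "ctiq_layout"), n_slices >= 1)
  plain <- render_slice(layout, with_lesion = FALSE)
  with_les <- render_slice(layout, with_lesion = TRUE)
  les <- lesion_slices(layout, n_slices, slice_thickness)
  vox <- array(plain, dim = c(dim(plain), n_slices))
  for (k in les) vox[, , k] <- with_les
  image_stack(vox, layout$pixel_spacing, slice_thickness,
              algorithm = "noiseless", scan_id = "render")
}

#' Gaussian blur of an image (frequency domain)
#'
#' Multiplies the image spectrum by the Gaussian transfer function
#' `exp(-2 pi^2 sigma^2 f^2)`; the corresponding point-spread function is an
#' isotropic Gaussian of standard deviation `sigma` mm. Periodic boundary
#' conditions (the phantom is surrounded by uniform air, so wrap-around is
#' inconsequential for interior structures).
#'
#' @param img numeric matrix.
#' @param sigma blur SD, mm; `<= 0` returns the input unchanged.
#' @param spacing pixel spacing, mm.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(img, sigma, spacing) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  fu <- fft_freqs(nr, spacing)
  fv <- fft_freqs(nc, spacing)
  f2 <- outer(fu^2, fv^2, "+")
  h <- exp(-2 * pi^2 * sigma^2 * f2)
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / (nr * nc)
}
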