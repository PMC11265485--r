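#' Construct a CT image stack
#'
#' The unit of analysis: an axial stack of CT images in Hounsfield units with
#' its acquisition metadata. Voxels are stored as a numeric array indexed
#' `[row, col, slice]`.
#'
#' @param voxels numeric array `rows x cols x slices` (a matrix is promoted to
#'   a single-slice stack), HU.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @param dose_ctdi dose (CTDI_vol), mGy; may be `NA` for noiseless renders.
#' @param algorithm reconstruction-algorithm label.
#' @param scan_id identifier string.
#' @param seed integer seed the stack was generated from, or `NA`.
#' @return An object of class `ctiq_stack`.
#' @export
image_stack <- function(voxels, pixel_spacing, slice_thickness,
                        dose_ctdi = NA_real_, algorithm = "unknown",
                        scan_id = "scan", seed = NA_integer_) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3)
  if (!all(is.finite(voxels))) stop("all voxels must be finite")
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be > 0")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be > 0")
  structure(list(voxels = voxels, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, dose_ctdi = dose_ctdi,
                 algorithm = algorithm, scan_id = scan_id, seed = seed),
            class = "ctiq_stack")
}

#' @export
print.ctiq_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ctiq stack '%s': %d slice(s) of %d x %d px @ %.4f mm, %g mm thick\n",
              x$scan_id, d[3], d[1], d[2], x$pixel_spacing, x$slice_thickness))
  cat(sprintf("  algorithm %s, dose %s mGy, seed %s\n", x$algorithm,
              format(x$dose_ctdi), format(x$seed)))
  invisible(x)
}

#' @export
dim.ctiq_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

get_slice <- function(stack, k) stack$voxels[, , k]

# z coordinate (mm, relative to stack centre) of each slice centre
slice_z <- function(n, thickness) (seq_len(n) - (n + 1) / 2) * thickness
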