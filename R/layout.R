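#' Phantom geometry
#'
#' Describes the semi-anthropomorphic upper-abdomen phantom emulated by the
#' simulator: an elliptical body (35 x 25 cm by default) containing a
#' homogeneous cylindrical insert (~58 HU) and a low-contrast insert
#' (~55 HU background) with a central lesion rod (~15 mm, ~80 HU) of limited
#' axial extent. All geometry is in millimetres relative to the image centre;
#' the physical position of pixel `(i, j)` (1-based row/column) is
#' `((j - (ncol+1)/2) * spacing, (i - (nrow+1)/2) * spacing)`.
#'
#' The default pixel spacing, 0.6854 mm, is back-computed from a 41-pixel ROI
#' spanning 28.1 mm; with a 512 x 512 grid it yields a 351 mm field of view
#' that just contains the 350 mm lateral body extent.
#'
#' @param grid_size integer vector `c(rows, cols)` of the image grid.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param body_semiaxes ellipse semi-axes `c(lateral, anterior-posterior)`, mm.
#' @param background_hu CT number of the phantom body material, HU.
#' @param insert_center,insert_diameter,insert_hu homogeneous insert: centre
#'   `c(x, y)` mm, diameter mm, CT number HU.
#' @param lowc_center,lowc_hu low-contrast insert centre and background HU.
#' @param lesion_diameter,lesion_hu,lesion_extent central lesion rod: diameter
#'   mm, CT number HU, axial (z) extent mm.
#' @param air_hu CT number assigned outside the body outline.
#' @return An object of class `ctiq_layout`.
#' @export
ctiq_layout <- function(grid_size = c(512L, 512L),
                        pixel_spacing = 0.6854,
                        body_semiaxes = c(175, 125),
                        background_hu = 18,
                        insert_center = c(-60, 0),
                        insert_diameter = 50,
                        insert_hu = 58,
                        lowc_center = c(60, 0),
                        lowc_hu = 55,
                        lesion_diameter = 15,
                        lesion_hu = 80,
                        lesion_extent = 30,
                        air_hu = -1000) {
  stopifnot(length(grid_size) == 2, length(body_semiaxes) == 2,
            length(insert_center) == 2, length(lowc_center) == 2)
  hu <- c(background_hu, insert_hu, lowc_hu, lesion_hu, air_hu)
  if (!all(is.finite(hu)))
    stop("all HU values must be finite")
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be > 0")
  if (any(grid_size < 2) || any(body_semiaxes <= 0))
    stop("invalid grid or body dimensions")
  if (lesion_diameter >= insert_diameter)
    stop("lesion must be smaller than its insert")

  layout <- structure(list(
    grid_size = as.integer(grid_size),
    pixel_spacing = pixel_spacing,
    body_semiaxes = body_semiaxes,
    background_hu = background_hu,
    insert_center = insert_center,
    insert_diameter = insert_diameter,
    insert_hu = insert_hu,
    lowc_center = lowc_center,
    lowc_hu = lowc_hu,
    lesion_diameter = lesion_diameter,
    lesion_hu = lesion_hu,
    lesion_extent = lesion_extent,
    air_hu = air_hu
  ), class = "ctiq_layout")

  # the grid must contain the body outline
  half_fov <- grid_size[c(2, 1)] / 2 * pixel_spacing  # (x, y) half extents
  if (body_semiaxes[1] > half_fov[1] || body_semiaxes[2] > half_fov[2])
    stop("grid too small to contain the body outline (",
         sprintf("body %g x %g mm, field of view %g x %g mm",
                 2 * body_semiaxes[1], 2 * body_semiaxes[2],
                 2 * half_fov[1], 2 * half_fov[2]), ")")
  for (ins in list(c(insert_center, insert_diameter / 2),
                   c(lowc_center, insert_diameter / 2))) {
    if (!circle_inside_ellipse(ins[1:2], ins[3], body_semiaxes))
      stop("insert at (", ins[1], ", ", ins[2],
           ") mm does not lie fully inside the body outline")
  }
  layout
}

# conservative containment check by sampling the circle boundary
circle_inside_ellipse <- function(center, radius, semiaxes, n = 360) {
  th <- seq(0, 2 * pi, length.out = n)
  x <- center[1] + radius * cos(th)
  y <- center[2] + radius * sin(th)
  all((x / semiaxes[1])^2 + (y / semiaxes[2])^2 <= 1)
}

#' @export
print.ctiq_layout <- function(x, ...) {
  cat("ctiq phantom layout\n")
  cat(sprintf("  grid: %d x %d px @ %.4f mm (FOV %.1f x %.1f mm)\n",
              x$grid_size[1], x$grid_size[2], x$pixel_spacing,
              x$grid_size[2] * x$pixel_spacing, x$grid_size[1] * x$pixel_spacing))
  cat(sprintf("  body ellipse: %g x %g mm semi-axes, %g HU (air %g HU)\n",
              x$body_semiaxes[1], x$body_semiaxes[2], x$background_hu, x$air_hu))
  cat(sprintf("  homogeneous insert: %g mm @ (%g, %g) mm, %g HU\n",
              x$insert_diameter, x$insert_center[1], x$insert_center[2], x$insert_hu))
  cat(sprintf("  low-contrast insert: %g HU, lesion %g mm / %g HU over %g mm in z\n",
              x$lowc_hu, x$lesion_diameter, x$lesion_hu, x$lesion_extent))
  invisible(x)
}

# mm coordinates (relative to image centre) of pixel centres along an axis
axis_mm <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Nearest pixel (row, col) for an (x, y) mm position
#'
#' Positions are in mm relative to the image centre; the returned indices are
#' 1-based.
#'
#' @param layout a [ctiq_layout()].
#' @param xy numeric `c(x, y)`, mm.
#' @return Numeric `c(row, col)`.
#' @export
mm_to_px <- function(layout, xy) {
  nr <- layout$grid_size[1]; nc <- layout$grid_size[2]; sp <- layout$pixel_spacing
  c(row = round(xy[2] / sp + (nr + 1) / 2),
    col = round(xy[1] / sp + (nc + 1) / 2))
}
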