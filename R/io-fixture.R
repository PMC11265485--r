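# Raw-array + JSON-sidecar fixture format.
#
# <scan_id>.raw : little-endian 32-bit floats, C order (slice, row, col)
# <scan_id>.json: pixel_spacing, slice_thickness, dose_ctdi, algorithm,
#                 scan_id, seed, dim = [slices, rows, cols]

sidecar_fields <- c("scan_id", "pixel_spacing", "slice_thickness",
                    "dose_ctdi", "algorithm", "seed", "dim")

#' Write an image stack as a raw + JSON fixture
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the path of the JSON sidecar.
#' @export
write_fixture <- function(stack, dir) {
  stopifnot(inherits(stack, "ctiq_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(stack$voxels)
  base <- file.path(dir, stack$scan_id)
  # C order (slice, row, col): fastest index col, then row, then slice
  v <- as.vector(aperm(stack$voxels, c(2, 1, 3)))
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4L, endian = "little")
  side <- list(scan_id = stack$scan_id, pixel_spacing = stack$pixel_spacing,
               slice_thickness = stack$slice_thickness,
               dose_ctdi = stack$dose_ctdi, algorithm = stack$algorithm,
               seed = stack$seed, dim = c(d[3], d[1], d[2]))
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paste0(base, ".json"))
}

#' Read an image stack from a raw + JSON fixture
#'
#' @param path path to the `.json` sidecar (or the basename without
#'   extension).
#' @return An [image_stack()].
#' @export
read_fixture <- function(path) {
  json_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  if (!file.exists(json_path)) stop("sidecar not found: ", json_path)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  missing <- setdiff(sidecar_fields, names(side))
  if (length(missing))
    stop("sidecar ", basename(json_path), " missing required field(s): ",
         paste(missing, collapse = ", "))
  d <- as.integer(side$dim)  # (slices, rows, cols)
  raw_path <- sub("\\.json$", ".raw", json_path)
  if (!file.exists(raw_path)) stop("raw array not found: ", raw_path)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  if (length(v) != prod(d))
    stop("raw array ", basename(raw_path), " has ", length(v),
         " values, expected ", prod(d))
  vox <- aperm(array(v, dim = c(d[3], d[2], d[1])), c(2, 1, 3))
  dose <- if (is.null(side$dose_ctdi)) NA_real_ else as.numeric(side$dose_ctdi)
  seed <- if (is.null(side$seed)) NA_integer_ else as.integer(side$seed)
  image_stack(vox, side$pixel_spacing, side$slice_thickness, dose,
              side$algorithm, side$scan_id, seed)
}
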