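# Minimal DICOM series writer/reader (explicit VR little endian, CT Image
# Storage), covering exactly the metadata contract of the fixture format:
# pixel spacing, slice thickness, dose (CTDIvol), algorithm label, scan id,
# seed, and rescale slope/intercept. Pixel data are stored as signed 16-bit
# integers, so HU round-trip to within 0.5 HU.

TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1474"

# VRs using the 4-byte length form
long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

int_le <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                     endian = "little")

dicom_element <- function(group, element, vr, value) {
  bytes <- switch(vr,
                  US = int_le(value, 2L),
                  UL = int_le(value, 4L),
                  FD = writeBin(as.numeric(value), raw(), size = 8L,
                                endian = "little"),
                  OB = , OW = as.raw(value),
                  {  # string VRs
                    b <- charToRaw(paste(value, collapse = "\\"))
                    if (length(b) %% 2 == 1)
                      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
                    b
                  })
  header <- c(int_le(group, 2L), int_le(element, 2L), charToRaw(vr))
  if (vr %in% long_vrs)
    c(header, as.raw(c(0L, 0L)), int_le(length(bytes), 4L), bytes)
  else c(header, int_le(length(bytes), 2L), bytes)
}

# deterministic numeric UID suffix from a string
uid_from_string <- function(s) {
  v <- utf8ToInt(s)
  paste0(sum(v * seq_along(v)) %% 99999989, ".", length(v))
}

#' Write an image stack as a DICOM series
#'
#' One explicit-VR little-endian CT Image Storage file per slice, named
#' `NNNNNN.dcm` in a directory named after the scan id. HU values are stored
#' as 16-bit integers with rescale intercept -1024 and slope 1 (quantization
#' at most 0.5 HU); dose is carried in the CTDIvol tag, the algorithm label
#' in SeriesDescription, the scan id in PatientID and the seed in
#' ImageComments.
#'
#' @param stack an [image_stack()].
#' @param dir parent directory; the series goes into `dir/<scan_id>/`.
#' @return Invisibly, the series directory path.
#' @export
write_dicom <- function(stack, dir) {
  stopifnot(inherits(stack, "ctiq_stack"))
  series_dir <- file.path(dir, stack$scan_id)
  if (!dir.exists(series_dir)) dir.create(series_dir, recursive = TRUE)
  d <- dim(stack$voxels)
  series_uid <- paste(UID_ROOT, uid_from_string(stack$scan_id), sep = ".")
  intercept <- -1024
  for (k in seq_len(d[3])) {
    sop_uid <- paste(series_uid, k, sep = ".")
    stored <- round(get_slice(stack, k)) - intercept
    if (any(stored < -32768 | stored > 32767))
      stop("HU values outside the 16-bit storage range")
    # pixel data in row-major (DICOM) order: rows of the image in sequence
    pix <- int_le(as.vector(t(stored)), 2L)
    meta_body <- c(
      dicom_element(0x0002, 0x0001, "OB", c(0L, 1L)),
      dicom_element(0x0002, 0x0002, "UI", SOP_CLASS_CT),
      dicom_element(0x0002, 0x0003, "UI", sop_uid),
      dicom_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_ELE),
      dicom_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1")))
    meta <- c(dicom_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
    dataset <- c(
      dicom_element(0x0008, 0x0016, "UI", SOP_CLASS_CT),
      dicom_element(0x0008, 0x0018, "UI", sop_uid),
      dicom_element(0x0008, 0x0060, "CS", "CT"),
      dicom_element(0x0008, 0x103E, "LO", stack$algorithm),
      dicom_element(0x0010, 0x0020, "LO", stack$scan_id),
      dicom_element(0x0018, 0x0050, "DS", format(stack$slice_thickness)),
      if (!is.na(stack$dose_ctdi))
        dicom_element(0x0018, 0x9345, "FD", stack$dose_ctdi),
      dicom_element(0x0020, 0x000E, "UI", series_uid),
      dicom_element(0x0020, 0x0013, "IS", as.character(k)),
      dicom_element(0x0020, 0x4000, "LT",
                    sprintf("seed=%s", format(stack$seed))),
      dicom_element(0x0028, 0x0002, "US", 1L),
      dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dicom_element(0x0028, 0x0010, "US", d[1]),
      dicom_element(0x0028, 0x0011, "US", d[2]),
      dicom_element(0x0028, 0x0030, "DS",
                    c(format(stack$pixel_spacing), format(stack$pixel_spacing))),
      dicom_element(0x0028, 0x0100, "US", 16L),
      dicom_element(0x0028, 0x0101, "US", 16L),
      dicom_element(0x0028, 0x0102, "US", 15L),
      dicom_element(0x0028, 0x0103, "US", 1L),
      dicom_element(0x0028, 0x1052, "DS", format(intercept)),
      dicom_element(0x0028, 0x1053, "DS", "1"),
      dicom_element(0x7FE0, 0x0010, "OW", pix))
    con <- file(file.path(series_dir, sprintf("%06d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
    close(con)
  }
  invisible(series_dir)
}

# parse one explicit-VR little-endian DICOM file into a tag list
parse_dicom_file <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 200 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  u16 <- function(i) readBin(buf[i:(i + 1)], "integer", size = 2L,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(buf[i:(i + 3)], "integer", size = 4L,
                             endian = "little")
  tags <- list()
  while (pos + 8 <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    val_raw <- if (len > 0) buf[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- switch(vr,
      US = readBin(val_raw, "integer", n = len / 2, size = 2L,
                   signed = FALSE, endian = "little"),
      UL = readBin(val_raw, "integer", n = len / 4, size = 4L,
                   endian = "little"),
      FD = readBin(val_raw, "numeric", n = len / 8, size = 8L,
                   endian = "little"),
      OW = , OB = val_raw,
      trimws(rawToChar(val_raw)))
    pos <- vstart + len
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts) && ts != TRANSFER_SYNTAX_ELE)
    stop("unsupported transfer syntax in ", path, ": ", ts)
  tags
}

#' Read a DICOM series as an image stack
#'
#' Reads every `*.dcm` file in a directory (explicit VR little endian,
#' uncompressed), orders slices by InstanceNumber, applies the rescale
#' slope/intercept to recover HU, and restores the metadata written by
#' [write_dicom()]. Files lacking pixel spacing, slice thickness or pixel
#' data are rejected with the missing attribute named.
#'
#' @param dir series directory.
#' @return An [image_stack()].
#' @export
read_dicom <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no .dcm files in ", dir)
  parsed <- lapply(files, parse_dicom_file)
  order_idx <- order(vapply(parsed, function(t)
    as.integer(t[["0020,0013"]] %||% NA_integer_), integer(1)))
  parsed <- parsed[order_idx]
  t1 <- parsed[[1]]
  need <- c("0028,0010" = "Rows", "0028,0011" = "Columns",
            "0028,0030" = "PixelSpacing", "0018,0050" = "SliceThickness",
            "7FE0,0010" = "PixelData")
  for (tag in names(need))
    if (is.null(t1[[tag]]))
      stop("DICOM series missing required attribute: ", need[[tag]])
  nr <- t1[["0028,0010"]]; nc <- t1[["0028,0011"]]
  spacing <- as.numeric(strsplit(t1[["0028,0030"]], "\\\\")[[1]][1])
  slices <- lapply(parsed, function(t) {
    slope <- as.numeric(t[["0028,1053"]] %||% "1")
    intercept <- as.numeric(t[["0028,1052"]] %||% "0")
    stored <- readBin(t[["7FE0,0010"]], "integer", n = nr * nc, size = 2L,
                      endian = "little")
    t(matrix(stored * slope + intercept, nc, nr))  # undo row-major storage
  })
  vox <- array(unlist(slices), dim = c(nr, nc, length(slices)))
  seed <- NA_integer_
  cm <- t1[["0020,4000"]]
  if (!is.null(cm) && grepl("^seed=-?[0-9]+$", cm))
    seed <- as.integer(sub("^seed=", "", cm))
  dose <- t1[["0018,9345"]]
  image_stack(vox, spacing, as.numeric(t1[["0018,0050"]]),
              dose_ctdi = if (is.null(dose)) NA_real_ else dose,
              algorithm = t1[["0008,103E"]] %||% "unknown",
              scan_id = t1[["0010,0020"]] %||% basename(dir),
              seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
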