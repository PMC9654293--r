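#' Construct a calibrated single-slice CT object
#'
#' The unit of image analysis: a 2-D grid of Hounsfield units with pixel
#' spacing and patient/timepoint metadata. HU values are stored as integers;
#' fractional inputs are rounded once at construction (ties away from zero),
#' because the band windows have integer bounds and integer HU makes the
#' band partition exact.
#'
#' @param hu numeric matrix of Hounsfield values.
#' @param pixel_spacing numeric length-2, mm per pixel along (row, col).
#' @param patient_id opaque identifier string.
#' @param timepoint `"diagnosis"` or `"followup"`.
#' @param acquisition_date a `Date` (or ISO-8601 string), optional.
#' @return An object of class `hu_slice`.
#' @export
hu_slice <- function(hu, pixel_spacing = c(1, 1), patient_id = NA_character_,
                     timepoint = c("diagnosis", "followup"),
                     acquisition_date = NULL) {
  timepoint <- match.arg(timepoint)
  if (!is.matrix(hu) || length(hu) == 0L)
    stop("hu must be a non-empty matrix", call. = FALSE)
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be positive in both axes", call. = FALSE)
  hu <- .round_half_away(hu)
  if (any(hu < -1024 | hu > 3071))
    stop("HU values outside the calibrated range [-1024, 3071]", call. = FALSE)
  storage.mode(hu) <- "integer"
  date <- if (is.null(acquisition_date)) as.Date(NA) else .parse_iso_date(acquisition_date)
  structure(list(hu = hu, pixel_spacing = pixel_spacing,
                 patient_id = patient_id, timepoint = timepoint,
                 acquisition_date = date),
            class = "hu_slice")
}

#' @export
print.hu_slice <- function(x, ...) {
  cat(sprintf("<hu_slice> %d x %d px, spacing %.3f x %.3f mm, HU [%d, %d]\n",
              nrow(x$hu), ncol(x$hu), x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$hu), max(x$hu)))
  cat(sprintf("  patient %s, %s, %s\n", x$patient_id, x$timepoint,
              format(x$acquisition_date)))
  invisible(x)
}

# round half away from zero (DICOM rescale calibration rounding rule here)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (any(is.na(d) & !is.na(x)))
    stop("dates must be ISO-8601 (YYYY-MM-DD)", call. = FALSE)
  d
}

#' Pixel area of a slice in cm-squared
#' @param slice an [hu_slice()].
#' @return Area of one pixel in cm2.
#' @export
pixel_area_cm2 <- function(slice) {
  prod(slice$pixel_spacing) / 100
}

#' Read a single CT slice
#'
#' Reads a calibrated 2-D Hounsfield grid from DICOM (single file), NIfTI
#' (2-D) or the plain-text `hugrid` fixture format. For DICOM,
#' `HU = stored * RescaleSlope + RescaleIntercept`, rounded to the nearest
#' integer with ties away from zero; missing rescale tags are an error
#' unless `assume_identity_rescale = TRUE`. Inputs with more than two
#' non-singleton dimensions are rejected: extract the L3 slice first.
#'
#' @param path file path.
#' @param format `"dicom"`, `"nifti"` or `"hugrid"`; inferred from the file
#'   extension when missing.
#' @param patient_id,timepoint,acquisition_date metadata for formats that do
#'   not carry them.
#' @param assume_identity_rescale if `TRUE`, a DICOM file without rescale
#'   tags is read with slope 1 and intercept 0 instead of erroring.
#' @return An [hu_slice()].
#' @export
read_slice <- function(path, format = c("auto", "dicom", "nifti", "hugrid"),
                       patient_id = NA_character_,
                       timepoint = "diagnosis",
                       acquisition_date = NULL,
                       assume_identity_rescale = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     dcm = "dicom", nii = "nifti", gz = "nifti",
                     hugrid = "hugrid", txt = "hugrid",
                     stop("cannot infer slice format from extension: ", path,
                          call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    hugrid = .read_hugrid(path, patient_id, timepoint, acquisition_date),
    nifti  = .read_nifti_slice(path, patient_id, timepoint, acquisition_date),
    dicom  = .read_dicom_slice(path, patient_id, timepoint, acquisition_date,
                               assume_identity_rescale))
}

#' Write a single CT slice
#'
#' Writes an [hu_slice()] as NIfTI 2-D, plain-text `hugrid`
#' (header: `rows cols spacing_row spacing_col`, then integer HU row-major)
#' or single-frame DICOM (explicit VR little endian, 16-bit signed,
#' rescale intercept -1024 / slope 1).
#'
#' @param slice an [hu_slice()].
#' @param path destination file.
#' @param format `"nifti"`, `"hugrid"` or `"dicom"`; inferred from the
#'   extension when missing.
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path,
                        format = c("auto", "nifti", "hugrid", "dicom")) {
  stopifnot(inherits(slice, "hu_slice"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     dcm = "dicom", nii = "nifti",
                     hugrid = "hugrid", txt = "hugrid",
                     stop("cannot infer slice format from extension: ", path,
                          call. = FALSE))
  }
  switch(format,
    hugrid = .write_hugrid(slice, path),
    nifti  = .write_nifti_slice(slice, path),
    dicom  = .write_dicom_slice(slice, path))
  invisible(path)
}

## ---- hugrid: plain-text fixture format -------------------------------------

.read_hugrid <- function(path, patient_id, timepoint, acquisition_date) {
  con <- file(path, "r"); on.exit(close(con))
  header <- scan(con, what = numeric(), n = 4, quiet = TRUE)
  if (length(header) != 4)
    stop("hugrid header must be: rows cols spacing_row spacing_col",
         call. = FALSE)
  nr <- as.integer(header[1]); nc <- as.integer(header[2])
  vals <- scan(con, what = integer(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("hugrid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  hu <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  hu_slice(hu, header[3:4], patient_id, timepoint, acquisition_date)
}

.write_hugrid <- function(slice, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat(sprintf("%d %d %.6g %.6g\n", nrow(slice$hu), ncol(slice$hu),
              slice$pixel_spacing[1], slice$pixel_spacing[2]), file = con)
  utils::write.table(slice$hu, con, row.names = FALSE, col.names = FALSE)
}

## ---- NIfTI -----------------------------------------------------------------

.read_nifti_slice <- function(path, patient_id, timepoint, acquisition_date) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  nonsingleton <- which(d > 1L)
  if (length(nonsingleton) > 2L)
    stop("input is 3-D or higher; pre-extract the L3 slice before reading",
         call. = FALSE)
  pd <- RNifti::pixdim(img)[1:2]
  dims <- if (length(nonsingleton) == 2L) d[nonsingleton] else c(d, 1L, 1L)[1:2]
  hu <- matrix(as.vector(arr), nrow = dims[1], ncol = dims[2]) # strip attrs
  hu_slice(hu, pd, patient_id, timepoint, acquisition_date)
}

.write_nifti_slice <- function(slice, path) {
  x <- slice$hu
  attr(x, "pixdim") <- slice$pixel_spacing
  RNifti::writeNifti(x, path, datatype = "int16")
}

## ---- minimal single-frame DICOM codec --------------------------------------
## Uncompressed little-endian only (explicit VR written; explicit or implicit
## read). Covers the tags a calibrated single-slice CT export needs.

.dicom_uid_explicit_le <- "1.2.840.10008.1.2.1"
.dicom_uid_implicit_le <- "1.2.840.10008.1.2"

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dicom_element <- function(group, element, vr, value) {
  # value already raw for binary VRs; character padded to even length
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  len <- length(value)
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32(len), value)
  } else {
    c(head, .u16(len), value)
  }
}

.write_dicom_slice <- function(slice, path) {
  hu <- slice$hu
  intercept <- -1024L
  stored <- as.integer(hu) - intercept          # >= 0, <= 4095
  # pixel data is row-major in DICOM; R matrices are column-major
  stored_rowmajor <- as.integer(t(hu)) - intercept
  pix <- writeBin(stored_rowmajor, raw(), size = 2, endian = "little")

  sop_class <- "1.2.840.10008.5.1.4.1.1.2"     # CT image storage
  sop_uid <- paste0("2.25.", paste(sample.int(9, 12, replace = TRUE) - 1L,
                                   collapse = ""))
  meta <- c(
    .dicom_element(0x0002, 0x0002, "UI", sop_class),
    .dicom_element(0x0002, 0x0003, "UI", sop_uid),
    .dicom_element(0x0002, 0x0010, "UI", .dicom_uid_explicit_le)
  )
  meta <- c(.dicom_element(0x0002, 0x0000, "UL", .u32(length(meta))), meta)

  ds <- c(
    .dicom_element(0x0008, 0x0016, "UI", sop_class),
    .dicom_element(0x0008, 0x0018, "UI", sop_uid),
    .dicom_element(0x0010, 0x0020, "LO", as.character(slice$patient_id)),
    .dicom_element(0x0028, 0x0002, "US", .u16(1)),
    .dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dicom_element(0x0028, 0x0010, "US", .u16(nrow(hu))),
    .dicom_element(0x0028, 0x0011, "US", .u16(ncol(hu))),
    .dicom_element(0x0028, 0x0030, "DS",
                   sprintf("%g\\%g", slice$pixel_spacing[1],
                           slice$pixel_spacing[2])),
    .dicom_element(0x0028, 0x0100, "US", .u16(16)),
    .dicom_element(0x0028, 0x0101, "US", .u16(16)),
    .dicom_element(0x0028, 0x0102, "US", .u16(15)),
    .dicom_element(0x0028, 0x0103, "US", .u16(1)),
    .dicom_element(0x0028, 0x1052, "DS", sprintf("%d", intercept)),
    .dicom_element(0x0028, 0x1053, "DS", "1"),
    .dicom_element(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
}

# parse one data element; returns list(group, element, vr, value(raw), next_offset)
.dicom_read_element <- function(bytes, off, explicit) {
  grp <- readBin(bytes[off + 0:1], "integer", size = 2, signed = FALSE,
                 endian = "little")
  ele <- readBin(bytes[off + 2:3], "integer", size = 2, signed = FALSE,
                 endian = "little")
  if (explicit) {
    vr <- rawToChar(bytes[off + 4:5])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- readBin(bytes[off + 8:11], "integer", size = 4, endian = "little")
      body <- off + 12L
    } else {
      len <- readBin(bytes[off + 6:7], "integer", size = 2, signed = FALSE,
                     endian = "little")
      body <- off + 8L
    }
  } else {
    vr <- NA_character_
    len <- readBin(bytes[off + 4:7], "integer", size = 4, endian = "little")
    body <- off + 8L
  }
  if (len < 0)
    stop("undefined-length DICOM element not supported by this reader",
         call. = FALSE)
  list(group = grp, element = ele, vr = vr,
       value = if (len > 0) bytes[body + 0:(len - 1L)] else raw(0),
       next_off = body + len)
}

.dicom_str <- function(raw) sub("[ \\0]+$", "", rawToChar(raw))

.read_dicom_slice <- function(path, patient_id, timepoint, acquisition_date,
                              assume_identity_rescale) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  off <- 1L
  if (length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM") {
    off <- 133L
    # file meta group is always explicit VR LE
    syntax <- .dicom_uid_explicit_le
    repeat {
      el <- .dicom_read_element(bytes, off, explicit = TRUE)
      if (el$group != 0x0002) break
      if (el$element == 0x0010) syntax <- .dicom_str(el$value)
      off <- el$next_off
    }
  } else {
    syntax <- .dicom_uid_implicit_le   # raw dataset, assume implicit LE
  }
  explicit <- switch(syntax,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2"   = FALSE,
    stop("unsupported DICOM transfer syntax: ", syntax, call. = FALSE))

  tags <- list()
  while (off <= length(bytes) - 7L) {
    el <- .dicom_read_element(bytes, off, explicit)
    key <- sprintf("%04x,%04x", el$group, el$element)
    tags[[key]] <- el
    off <- el$next_off
    if (el$group == 0x7FE0 && el$element == 0x0010) break
  }

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("DICOM missing ", what, " (", key, ")",
                                   call. = FALSE)
    tags[[key]]
  }
  us <- function(el) readBin(el$value[1:2], "integer", size = 2,
                             signed = FALSE, endian = "little")
  rows <- us(need("0028,0010", "Rows"))
  cols <- us(need("0028,0011", "Columns"))
  bits <- us(need("0028,0100", "BitsAllocated"))
  if (bits != 16L) stop("only 16-bit DICOM pixel data supported", call. = FALSE)
  signed <- !is.null(tags[["0028,0103"]]) && us(tags[["0028,0103"]]) == 1L
  spacing <- if (!is.null(tags[["0028,0030"]])) {
    as.numeric(strsplit(.dicom_str(tags[["0028,0030"]]$value), "\\\\")[[1]])
  } else c(1, 1)

  if (is.null(tags[["0028,1052"]]) || is.null(tags[["0028,1053"]])) {
    if (!assume_identity_rescale)
      stop(paste("DICOM lacks rescale slope/intercept tags; refusing to",
                 "assume identity calibration (set assume_identity_rescale",
                 "= TRUE to override)"), call. = FALSE)
    intercept <- 0; slope <- 1
  } else {
    intercept <- as.numeric(.dicom_str(tags[["0028,1052"]]$value))
    slope <- as.numeric(.dicom_str(tags[["0028,1053"]]$value))
  }

  pix <- need("7fe0,0010", "PixelData")
  stored <- readBin(pix$value, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  if (!signed) stored[stored < 0] <- stored[stored < 0] + 65536L
  hu <- .round_half_away(stored * slope + intercept)
  hu <- matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)
  pid <- patient_id
  if (is.na(pid) && !is.null(tags[["0010,0020"]]))
    pid <- .dicom_str(tags[["0010,0020"]]$value)
  hu_slice(hu, spacing, pid, timepoint, acquisition_date)
}

## ---- mask QC export --------------------------------------------------------

#' Export compartment masks as a PNG overlay for visual QC
#'
#' Greyscale body outline with the subcutaneous, muscle-wall and visceral
#' compartments in distinct intensities.
#'
#' @param masks a `compartment_masks` object from [separate_compartments()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_mask_png <- function(masks, path) {
  img <- matrix(0, nrow = nrow(masks$body), ncol = ncol(masks$body))
  img[masks$body] <- 0.25
  img[masks$subcut_region] <- 0.5
  img[masks$musclewall_region] <- 0.75
  img[masks$visceral_region] <- 1
  EBImage::writeImage(EBImage::Image(img), path)
  invisible(path)
}
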