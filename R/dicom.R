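# Minimal DICOM codec: explicit-VR little-endian, single-frame grayscale,
# covering the header attributes the curation pipeline filters on. Writing
# produces standard Part-10 files (128-byte preamble, "DICM", group-0002 file
# meta with the explicit-VR-LE transfer syntax) readable by pydicom et al.;
# reading parses the same subset back.

DICOM_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"
DICOM_MR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.4"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_pad <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

dcm_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(paste(value, collapse = "\\"))
    v <- dcm_pad(v, if (vr == "UI") as.raw(0x00) else as.raw(0x20))
  } else if (vr == "US") {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    v <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr %in% c("OW", "OB")) {
    v <- value  # already raw
  } else stop("unsupported VR for non-character value: ", vr)
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2,
                     endian = "little"),
            charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(v), raw(), size = 4, endian = "little"), v)
  } else {
    c(head, writeBin(length(v), raw(), size = 2, endian = "little"), v)
  }
}

orientation_to_iop <- function(orientation) {
  switch(orientation,
         sagittal = c(0, 1, 0, 0, 0, -1),
         coronal = c(1, 0, 0, 0, 0, -1),
         axial = c(1, 0, 0, 0, 1, 0),
         stop("unknown orientation: ", orientation))
}

iop_to_orientation <- function(iop) {
  if (length(iop) != 6 || anyNA(iop)) return(NA_character_)
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  axis <- which.max(abs(normal))
  c("sagittal", "coronal", "axial")[axis]
}

num_or_string <- function(x) {
  if (is.character(x)) x
  else format(x, trim = TRUE, scientific = FALSE, digits = 12)
}

#' Write a single-slice MR DICOM file
#'
#' @param path Output file path.
#' @param pixels Square numeric matrix in \[-1, 1\] (or any range; values are
#'   linearly mapped onto the 16-bit integer range \[0, 65535\] from
#'   \[-1, 1\]).
#' @param tr,te Repetition and echo time in ms (numeric, or character to
#'   write a malformed value on purpose).
#' @param orientation `"sagittal"`, `"coronal"` or `"axial"`; stored as the
#'   standard image-orientation direction cosines.
#' @param field_strength Magnetic field strength in tesla.
#' @param manufacturer Manufacturer string, or `NA` to omit the attribute.
#' @param coil_name Receive-coil name, or `NA` to omit.
#' @param fat_sat Logical; when `TRUE` the scan-options attribute carries the
#'   fat-saturation flag (`"FS"`).
#' @param study_uid,series_uid,instance Study/series identifiers and instance
#'   number.
#' @return `path`, invisibly.
#' @export
dcm_write <- function(path, pixels, tr, te, orientation = "sagittal",
                      field_strength = 1.5, manufacturer = "SIEMENS",
                      coil_name = "Tx_Rx_Knee_Siemens", fat_sat = FALSE,
                      study_uid = "1.2.826.0.1.3680043.9999.1",
                      series_uid = paste0(study_uid, ".1"), instance = 1L) {
  stopifnot(is.matrix(pixels))
  sop_uid <- paste0(series_uid, ".", instance)
  u16 <- as.integer(round(pmin(pmax((pixels + 1) / 2, 0), 1) * 65535))
  pix_raw <- writeBin(u16, raw(), size = 2, endian = "little")

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", DICOM_MR_SOP_CLASS),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", DICOM_TRANSFER_SYNTAX),
    dcm_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.0.1"))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)

  body <- c(
    dcm_element(0x0008, 0x0016, "UI", DICOM_MR_SOP_CLASS),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "MR"))
  if (!is.na(manufacturer))
    body <- c(body, dcm_element(0x0008, 0x0070, "LO", manufacturer))
  body <- c(body,
    dcm_element(0x0018, 0x0020, "CS", "SE"),
    dcm_element(0x0018, 0x0022, "CS", if (fat_sat) "FS" else "NONE"),
    dcm_element(0x0018, 0x0080, "DS", num_or_string(tr)),
    dcm_element(0x0018, 0x0081, "DS", num_or_string(te)),
    dcm_element(0x0018, 0x0087, "DS", num_or_string(field_strength)))
  if (!is.na(coil_name))
    body <- c(body, dcm_element(0x0018, 0x1250, "SH", coil_name))
  body <- c(body,
    dcm_element(0x0020, 0x000D, "UI", study_uid),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0037, "DS",
                format(orientation_to_iop(orientation), trim = TRUE)),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(pixels)),
    dcm_element(0x0028, 0x0011, "US", ncol(pixels)),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_u16 <- function(r, at) {
  as.integer(r[at]) + 256L * as.integer(r[at + 1L])
}
read_u32 <- function(r, at) {
  as.integer(r[at]) + 256 * as.integer(r[at + 1L]) +
    65536 * as.integer(r[at + 2L]) + 16777216 * as.integer(r[at + 3L])
}

parse_ds <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\\\")[[1]]))
  v
}

#' Read a DICOM file written in explicit-VR little-endian
#'
#' Parses the header attributes used by the curation pipeline and optionally
#' the pixel data.
#'
#' @param path File path.
#' @param pixels Read the pixel data too (default `TRUE`).
#' @return A list with `tr`, `te` (ms, `NA` when malformed),
#'   `field_strength`, `manufacturer`, `coil_name` (`NA` when absent),
#'   `scan_options`, `orientation`, `study_uid`, `series_uid`, `instance`,
#'   `rows`, `cols`, and (when requested) `pixels`, a matrix scaled back to
#'   \[-1, 1\].
#' @export
dcm_read <- function(path, pixels = TRUE) {
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list(tr = NA_real_, te = NA_real_, field_strength = NA_real_,
              manufacturer = NA_character_, coil_name = NA_character_,
              scan_options = "", orientation = NA_character_,
              study_uid = NA_character_, series_uid = NA_character_,
              instance = NA_integer_, rows = NA_integer_, cols = NA_integer_)
  pix_raw <- NULL
  while (pos + 8L <= length(r) + 1L) {
    group <- read_u16(r, pos)
    element <- read_u16(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(r, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- read_u16(r, pos + 6L)
      vstart <- pos + 8L
    }
    val <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    txt <- function() trimws(rawToChar(val[val != as.raw(0)]))
    switch(key,
      "0008,0070" = { out$manufacturer <- txt() },
      "0018,0022" = { out$scan_options <- txt() },
      "0018,0080" = { out$tr <- parse_ds(txt())[1] },
      "0018,0081" = { out$te <- parse_ds(txt())[1] },
      "0018,0087" = { out$field_strength <- parse_ds(txt())[1] },
      "0018,1250" = { out$coil_name <- txt() },
      "0020,000D" = { out$study_uid <- txt() },
      "0020,000E" = { out$series_uid <- txt() },
      "0020,0013" = { out$instance <- suppressWarnings(as.integer(txt())) },
      "0020,0037" = { out$orientation <- iop_to_orientation(parse_ds(txt())) },
      "0028,0010" = { out$rows <- read_u16(val, 1L) },
      "0028,0011" = { out$cols <- read_u16(val, 1L) },
      "7FE0,0010" = { pix_raw <- val },
      NULL)
    pos <- vstart + len
    if (!is.null(pix_raw)) break
  }
  if (pixels && !is.null(pix_raw) && !is.na(out$rows)) {
    u16 <- readBin(pix_raw, integer(), n = length(pix_raw) / 2L, size = 2,
                   endian = "little", signed = FALSE)
    out$pixels <- matrix(u16 / 65535 * 2 - 1, out$rows, out$cols)
  }
  out
}
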