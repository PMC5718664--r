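# Minimal DICOM Part-10 I/O for single-frame axial CT slices.
# Supported transfer syntaxes: Explicit and Implicit VR Little Endian,
# uncompressed.  This covers what the emulated scanners export; compressed
# syntaxes, multi-frame objects and networking are out of scope.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1464."

# long-form VRs carry a 2-byte reserved field and 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# tags this package reads back, with their VR (for implicit-VR decoding)
DCM_DICT <- list(
  "0008,0016" = c("SOPClassUID", "UI"),
  "0008,0018" = c("SOPInstanceUID", "UI"),
  "0008,0060" = c("Modality", "CS"),
  "0008,103e" = c("SeriesDescription", "LO"),
  "0018,0050" = c("SliceThickness", "DS"),
  "0018,0060" = c("KVP", "DS"),
  "0020,000d" = c("StudyInstanceUID", "UI"),
  "0020,000e" = c("SeriesInstanceUID", "UI"),
  "0020,0011" = c("SeriesNumber", "IS"),
  "0020,0013" = c("InstanceNumber", "IS"),
  "0020,0032" = c("ImagePositionPatient", "DS"),
  "0020,0037" = c("ImageOrientationPatient", "DS"),
  "0028,0002" = c("SamplesPerPixel", "US"),
  "0028,0004" = c("PhotometricInterpretation", "CS"),
  "0028,0010" = c("Rows", "US"),
  "0028,0011" = c("Columns", "US"),
  "0028,0030" = c("PixelSpacing", "DS"),
  "0028,0100" = c("BitsAllocated", "US"),
  "0028,0101" = c("BitsStored", "US"),
  "0028,0102" = c("HighBit", "US"),
  "0028,0103" = c("PixelRepresentation", "US"),
  "0028,1052" = c("RescaleIntercept", "DS"),
  "0028,1053" = c("RescaleSlope", "DS"),
  "7fe0,0010" = c("PixelData", "OW"))

u16_raw <- function(x) {
  x <- as.integer(round(x))
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2, endian = "little")
}
u32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

ascii_raw <- function(s, pad_null = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, if (pad_null) as.raw(0) else charToRaw(" "))
  r
}

# drop trailing nul/space padding before text decode
raw_to_text <- function(val_raw) {
  trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
}

dcm_element <- function(group, elem, vr, value) {
  hdr <- c(u16_raw(group), u16_raw(elem))
  if (vr %in% LONG_VRS)
    c(hdr, charToRaw(vr), as.raw(c(0, 0)), u32_raw(length(value)), value)
  else
    c(hdr, charToRaw(vr), u16_raw(length(value)), value)
}

dcm_value <- function(vr, x) {
  switch(vr,
         UI = ascii_raw(paste(x, collapse = "\\"), pad_null = TRUE),
         US = u16_raw(x),
         UL = u32_raw(x),
         OB = as.raw(x),
         OW = as.raw(x),
         DS = ascii_raw(paste(formatC(x, format = "fg", digits = 10), collapse = "\\")),
         IS = ascii_raw(paste(as.integer(x), collapse = "\\")),
         ascii_raw(paste(x, collapse = "\\")))   # CS/LO/SH/...
}

dcm_write_slice <- function(path, pixels, meta) {
  # pixels: integer matrix [row, col], unsigned 16-bit
  px_raw <- u16_raw(as.integer(t(pixels)))
  el <- function(g, e, vr, x) dcm_element(g, e, vr, dcm_value(vr, x))
  ds <- c(
    el(0x0008, 0x0016, "UI", CT_SOP_CLASS),
    el(0x0008, 0x0018, "UI", meta$sop_instance_uid),
    el(0x0008, 0x0060, "CS", "CT"),
    el(0x0008, 0x103e, "LO", meta$series_description),
    el(0x0018, 0x0050, "DS", meta$slice_thickness),
    el(0x0018, 0x0060, "DS", meta$kvp),
    el(0x0020, 0x000d, "UI", meta$study_uid),
    el(0x0020, 0x000e, "UI", meta$series_uid),
    el(0x0020, 0x0011, "IS", 1L),
    el(0x0020, 0x0013, "IS", meta$instance_number),
    el(0x0020, 0x0032, "DS", meta$image_position),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0028, 0x0002, "US", 1L),
    el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el(0x0028, 0x0010, "US", nrow(pixels)),
    el(0x0028, 0x0011, "US", ncol(pixels)),
    el(0x0028, 0x0030, "DS", meta$pixel_spacing),   # row, col
    el(0x0028, 0x0100, "US", 16L),
    el(0x0028, 0x0101, "US", 16L),
    el(0x0028, 0x0102, "US", 15L),
    el(0x0028, 0x0103, "US", 0L),
    el(0x0028, 0x1052, "DS", meta$rescale_intercept),
    el(0x0028, 0x1053, "DS", meta$rescale_slope),
    dcm_element(0x7fe0, 0x0010, "OW", px_raw))
  fm <- c(
    el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el(0x0002, 0x0002, "UI", CT_SOP_CLASS),
    el(0x0002, 0x0003, "UI", meta$sop_instance_uid),
    el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    el(0x0002, 0x0012, "UI", paste0(UID_ROOT, "1")))
  out <- c(raw(128), charToRaw("DICM"),
           el(0x0002, 0x0000, "UL", length(fm)), fm, ds)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

read_u16 <- function(r, i) {
  readBin(r[i:(i + 1)], "integer", size = 2, endian = "little", signed = FALSE)
}
read_u32 <- function(r, i) {
  v <- readBin(r[i:(i + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# parse one dataset; returns named list of decoded elements
dcm_parse <- function(r, pos, explicit, stop_group = NULL) {
  out <- list()
  n <- length(r)
  while (pos + 7 <= n + 1 && pos <= n - 7) {
    group <- read_u16(r, pos)
    elem <- read_u16(r, pos + 2)
    if (!is.null(stop_group) && group != stop_group) break
    if (explicit) {
      vr <- rawToChar(r[(pos + 4):(pos + 5)])
      if (vr %in% LONG_VRS) {
        len <- read_u32(r, pos + 8)
        vpos <- pos + 12
      } else {
        len <- read_u16(r, pos + 6)
        vpos <- pos + 8
      }
    } else {
      len <- read_u32(r, pos + 4)
      vpos <- pos + 8
      vr <- NA_character_
    }
    key <- sprintf("%04x,%04x", group, elem)
    if (is.na(vr) || vr == "") vr <- DCM_DICT[[key]][2] %||% "UN"
    if (len == 0xFFFFFFFF)
      stop_qa("malformed_series", "undefined-length element %s not supported", key)
    val_raw <- if (len > 0) r[vpos:(vpos + len - 1)] else raw(0)
    info <- DCM_DICT[[key]]
    if (!is.null(info)) {
      val <- switch(vr,
        US = readBin(val_raw, "integer", n = len / 2, size = 2,
                     endian = "little", signed = FALSE),
        OW = val_raw,
        OB = val_raw,
        DS = as.numeric(strsplit(raw_to_text(val_raw), "\\", fixed = TRUE)[[1]]),
        IS = as.integer(strsplit(raw_to_text(val_raw), "\\", fixed = TRUE)[[1]]),
        raw_to_text(val_raw))
      out[[info[1]]] <- val
    }
    pos <- vpos + len
  }
  attr(out, "end_pos") <- pos
  out
}

dcm_read_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop_qa("not_dicom", "%s is not a DICOM Part-10 file", basename(path))
  meta <- dcm_parse(r, 133, explicit = TRUE, stop_group = 0x0002)
  ts <- dcm_parse_meta_ts(r) %||% TS_EXPLICIT_LE
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
    stop_qa("malformed_series", "unsupported transfer syntax %s in %s", ts, basename(path))
  ds <- dcm_parse(r, attr(meta, "end_pos"), explicit = ts == TS_EXPLICIT_LE)
  ds
}

# extract (0002,0010) transfer syntax from the file meta group
dcm_parse_meta_ts <- function(r) {
  pos <- 133
  n <- length(r)
  while (pos <= n - 7) {
    group <- read_u16(r, pos)
    elem <- read_u16(r, pos + 2)
    if (group != 0x0002) return(NULL)
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(r, pos + 8); vpos <- pos + 12
    } else {
      len <- read_u16(r, pos + 6); vpos <- pos + 8
    }
    if (elem == 0x0010) return(raw_to_text(r[vpos:(vpos + len - 1)]))
    pos <- vpos + len
  }
  NULL
}

#' Write a CT volume as a DICOM series
#'
#' Writes one single-frame CT Image Storage file per slice (Explicit VR
#' Little Endian, unsigned 16-bit pixels), recording rescale slope and
#' intercept, pixel spacing, slice thickness and axial positions so the
#' series round-trips bit-exactly through [read_series()].
#'
#' @param volume A `volume_image`.
#' @param dir Output directory (created if needed).
#' @param series_description Free-text series description tag.
#' @param uid_seed Integer mixed into the generated UIDs so repeated runs
#'   are deterministic.
#' @return Character vector of written file paths, invisibly.
#' @export
write_series <- function(volume, dir, series_description = "catphanqa", uid_seed = 0L) {
  stopifnot(inherits(volume, "volume_image"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_qa("io_error", "cannot create directory %s", dir)
  d <- dim(volume$stored)
  series_uid <- paste0(UID_ROOT, uid_seed, ".1")
  study_uid <- paste0(UID_ROOT, uid_seed, ".0")
  kvp <- volume$meta$kvp %||% 120
  dz <- if (d[3] > 1) min(diff(sort(volume$slice_z))) else volume$voxel_size[3]
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    meta <- list(
      sop_instance_uid = paste0(UID_ROOT, uid_seed, ".2.", k),
      series_description = series_description,
      slice_thickness = volume$voxel_size[3],
      kvp = kvp,
      study_uid = study_uid, series_uid = series_uid,
      instance_number = k,
      image_position = c(volume$origin[1], volume$origin[2], volume$slice_z[k]),
      pixel_spacing = c(volume$voxel_size[2], volume$voxel_size[1]),  # row, col
      rescale_intercept = volume$rescale_intercept,
      rescale_slope = volume$rescale_slope)
    files[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    dcm_write_slice(files[k], volume$stored[, , k], meta)
  }
  invisible(files)
}

#' Read an axial DICOM CT series from a directory
#'
#' Reads every parseable single-frame DICOM file in `dir`, orders slices
#' by axial position (Image Position Patient z, falling back to instance
#' number), and assembles a [volume_image()].  Non-DICOM files are skipped
#' with a warning; missing rescale tags default to slope 1 / intercept 0
#' with a warning.
#'
#' @param dir Directory containing the series.
#' @return A `volume_image`.
#' @export
read_series <- function(dir) {
  if (!dir.exists(dir)) stop_qa("not_found", "directory %s does not exist", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files) & basename(files) != "manifest.json"]
  if (length(files) == 0) stop_qa("not_found", "no files in %s", dir)
  slices <- list()
  for (f in files) {
    ds <- tryCatch(dcm_read_file(f), error = function(e) {
      warning(sprintf("skipping %s: %s", basename(f), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(ds)) slices[[length(slices) + 1]] <- ds
  }
  if (length(slices) == 0)
    stop_qa("not_found", "no readable DICOM slices in %s", dir)
  dims <- vapply(slices, function(s) c(s$Rows, s$Columns), c(0, 0))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_qa("malformed_series", "inconsistent image shapes across slices")
  z <- vapply(slices, function(s)
    if (!is.null(s$ImagePositionPatient)) s$ImagePositionPatient[3]
    else as.numeric(s$InstanceNumber %||% NA_real_), 0)
  if (anyNA(z)) stop_qa("malformed_series", "slices lack axial position information")
  if (anyDuplicated(z)) stop_qa("malformed_series", "duplicate axial slice positions")
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  s1 <- slices[[1]]
  if (is.null(s1$RescaleSlope) || is.null(s1$RescaleIntercept))
    warning("rescale tags missing; defaulting to slope 1, intercept 0", call. = FALSE)
  slope <- (s1$RescaleSlope %||% 1)[1]
  intercept <- (s1$RescaleIntercept %||% 0)[1]
  nr <- s1$Rows; nc <- s1$Columns
  signed <- identical(s1$PixelRepresentation, 1L)
  stored <- array(0L, c(nr, nc, length(slices)))
  for (k in seq_along(slices)) {
    px <- readBin(slices[[k]]$PixelData, "integer", n = nr * nc, size = 2,
                  endian = "little", signed = signed)
    stored[, , k] <- matrix(px, nr, nc, byrow = TRUE)
  }
  ps <- s1$PixelSpacing %||% c(1, 1)       # row, col
  dz <- if (length(z) > 1) min(diff(z)) else (s1$SliceThickness %||% 1)[1]
  ipp <- s1$ImagePositionPatient %||% c(0, 0, z[1])
  volume_image(stored, rescale_slope = slope, rescale_intercept = intercept,
               voxel_size = c(ps[2], ps[1], (s1$SliceThickness %||% dz)[1]),
               origin = ipp[1:2], slice_z = z,
               meta = list(series_description = s1$SeriesDescription,
                           kvp = (s1$KVP %||% NA_real_)[1],
                           series_uid = s1$SeriesInstanceUID))
}
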