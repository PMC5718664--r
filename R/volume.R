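#' Stored-pixel CT volume with rescale metadata
#'
#' Container for a 3-D stack of axial CT slices as stored (unsigned
#' integer) pixel values plus the DICOM rescale metadata needed to map
#' them to CT numbers: `CT = pix * RescaleSlope + RescaleIntercept`.
#'
#' Indexing convention: `stored[row, col, slice]`, with `row` along the
#' patient y axis and `col` along x.  `origin` is the physical (x, y)
#' position (mm) of the centre of the first voxel of each slice;
#' `slice_z` gives each slice's axial position (mm), increasing with
#' slice index.
#'
#' @param stored 3-D array of non-negative integer stored pixel values.
#' @param rescale_slope,rescale_intercept Rescale mapping to HU.
#' @param voxel_size Numeric triple (x, y, z) voxel dimensions in mm.
#' @param origin Numeric pair, physical (x, y) of the first voxel centre (mm).
#' @param slice_z Axial positions of the slices (mm); defaults to
#'   `0, dz, 2 dz, ...`.
#' @param meta Named list of free-form series metadata.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(stored, rescale_slope = 1, rescale_intercept = -1000,
                         voxel_size = c(1, 1, 1), origin = c(0, 0),
                         slice_z = NULL, meta = list()) {
  stored <- as.array(stored)
  if (length(dim(stored)) == 2L) dim(stored) <- c(dim(stored), 1L)
  stopifnot(length(dim(stored)) == 3L)
  if (any(stored < 0) || any(stored != round(stored)))
    stop_qa("invalid_volume", "stored pixels must be non-negative integers")
  if (any(stored > 65535))
    stop_qa("invalid_volume", "stored pixels exceed 16-bit range")
  if (any(voxel_size <= 0))
    stop_qa("invalid_volume", "voxel_size components must be positive")
  nz <- dim(stored)[3]
  slice_z <- slice_z %||% ((seq_len(nz) - 1) * voxel_size[3])
  stopifnot(length(slice_z) == nz, length(origin) >= 2)
  structure(list(stored = stored,
                 rescale_slope = rescale_slope,
                 rescale_intercept = rescale_intercept,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin[1:2]),
                 slice_z = as.numeric(slice_z),
                 meta = meta),
            class = "volume_image")
}

#' Convert stored pixels to CT numbers (HU)
#'
#' Applies the elementwise rescale `pix * RescaleSlope + RescaleIntercept`.
#'
#' @param volume A `volume_image`.
#' @return 3-D numeric array of CT numbers (HU), same shape as the stored
#'   pixels.
#' @examples
#' v <- volume_image(array(0L, c(2, 2, 1)), rescale_intercept = -1000)
#' to_ct_numbers(v)[1, 1, 1]   # -1000
#' @export
to_ct_numbers <- function(volume) {
  stopifnot(inherits(volume, "volume_image"))
  volume$stored * volume$rescale_slope + volume$rescale_intercept
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$stored)
  cat(sprintf("CT volume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, slope %g, intercept %g\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$rescale_slope, x$rescale_intercept))
  invisible(x)
}

# Working representation for synthesis/analysis: CT numbers in HU plus
# geometry; optionally carries a material-label array and the phantom it
# was rendered from.
qa_volume <- function(ct, voxel_size, origin = c(0, 0), slice_z = NULL,
                      labels = NULL, label_levels = NULL, phantom = NULL) {
  ct <- as.array(ct)
  if (length(dim(ct)) == 2L) dim(ct) <- c(dim(ct), 1L)
  nz <- dim(ct)[3]
  slice_z <- slice_z %||% ((seq_len(nz) - 1) * voxel_size[3])
  structure(list(ct = ct, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin[1:2]), slice_z = as.numeric(slice_z),
                 labels = labels, label_levels = label_levels,
                 phantom = phantom),
            class = "qa_volume")
}

#' Interpret a stored-pixel volume as CT numbers for analysis
#'
#' @param x A `volume_image` or `qa_volume`.
#' @param phantom Optional `phantom_definition` to attach.
#' @return A `qa_volume` holding CT numbers in HU.
#' @export
as_qa_volume <- function(x, phantom = NULL) {
  if (inherits(x, "qa_volume")) {
    if (!is.null(phantom)) x$phantom <- phantom
    return(x)
  }
  stopifnot(inherits(x, "volume_image"))
  qa_volume(to_ct_numbers(x), voxel_size = x$voxel_size, origin = x$origin,
            slice_z = x$slice_z, phantom = phantom)
}

# physical in-plane coordinates of voxel centres for a slice
plane_coords <- function(vol) {
  d <- dim(vol$ct %||% vol$stored)
  list(x = vol$origin[1] + (seq_len(d[2]) - 1) * vol$voxel_size[1],
       y = vol$origin[2] + (seq_len(d[1]) - 1) * vol$voxel_size[2])
}

#' Encode a CT-number volume as stored pixels
#'
#' Quantizes HU values to integer stored pixels with the given rescale
#' (`stored = round(HU - intercept)` for slope 1), clamped to the unsigned
#' 16-bit range, emulating how the scanners export DICOM slices.
#'
#' @param vol A `qa_volume` (HU).
#' @param rescale_intercept Intercept to encode with (−1000 emulates OBI,
#'   −510 emulates XVI).
#' @param rescale_slope Slope (1 for both emulated systems).
#' @param meta Metadata list to attach.
#' @return A `volume_image`.
#' @export
encode_volume <- function(vol, rescale_intercept = -1000, rescale_slope = 1,
                          meta = list()) {
  stopifnot(inherits(vol, "qa_volume"))
  stored <- round((vol$ct - rescale_intercept) / rescale_slope)
  stored[stored < 0] <- 0
  stored[stored > 65535] <- 65535
  storage.mode(stored) <- "integer"
  volume_image(stored, rescale_slope, rescale_intercept,
               voxel_size = vol$voxel_size, origin = vol$origin,
               slice_z = vol$slice_z, meta = meta)
}
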