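# Measurement procedures on CATPHAN scans: the phantom is located by
# thresholding, circular ROIs are placed from the phantom geometry, and
# the image-quality indices are computed from ROI means and standard
# deviations on the central slice of each module (optionally averaged
# over a few adjacent slices).

resolve_vol <- function(x, phantom = NULL) {
  v <- as_qa_volume(x, phantom)
  if (is.null(v$phantom))
    stop_qa("configuration_error",
            "a phantom_definition is required (pass `phantom` or use a rendered volume)")
  v
}

# slice indices to analyse for a module: the n_slices nearest the module
# centre, all within the module's axial extent
module_slices <- function(vol, kind, n_slices = 1) {
  m <- phantom_module(vol$phantom, kind)
  if (is.null(m))
    stop_qa("configuration_error", "phantom has no %s module", kind)
  dzs <- abs(vol$slice_z - m$z_offset)
  ok <- which(dzs <= vol$phantom$module_thickness_mm / 2)
  if (length(ok) == 0)
    stop_qa("configuration_error", "no slices cover module %s", kind)
  ok[order(dzs[ok])][seq_len(min(n_slices, length(ok)))]
}

#' Locate the phantom centre on an axial slice
#'
#' Returns the centroid, in physical coordinates, of the largest
#' connected foreground component of the thresholded slice — an automated
#' surrogate for aligning the phantom's radio-opaque markers with the
#' room lasers.  The default threshold adapts to the slice (minimum plus
#' 10% of the dynamic range), so the result is invariant under global
#' additive shifts of the CT numbers — important for XVI scans, whose
#' pixel values are not calibrated CT numbers and drift with mAs.
#' Keeping only the largest connected component discards isolated noise
#' voxels in the surrounding air.
#'
#' @param x A `volume_image` or `qa_volume`.
#' @param slice Slice index (default 1).
#' @param threshold Foreground threshold (HU); adaptive when `NULL`.
#' @param phantom Optional `phantom_definition`.
#' @return Numeric `(x, y)` centre in mm.
#' @export
locate_center <- function(x, slice = 1, threshold = NULL, phantom = NULL) {
  vol <- as_qa_volume(x, phantom)
  img <- vol$ct[, , slice]
  threshold <- threshold %||% (min(img) + 0.1 * (max(img) - min(img)))
  mask <- img > threshold
  if (!any(mask)) stop_qa("phantom_not_found", "no foreground above %g HU", threshold)
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  pc <- plane_coords(vol)
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(pc$x[idx[, 2]]), y = mean(pc$y[idx[, 1]]))
}

roi_values <- function(vol, center, diameter, slice) {
  pc <- plane_coords(vol)
  d2 <- outer((pc$y - center[2])^2, (pc$x - center[1])^2, `+`)
  rad <- diameter / 2
  if (center[1] - rad < pc$x[1] - vol$voxel_size[1] / 2 ||
      center[1] + rad > pc$x[length(pc$x)] + vol$voxel_size[1] / 2 ||
      center[2] - rad < pc$y[1] - vol$voxel_size[2] / 2 ||
      center[2] + rad > pc$y[length(pc$y)] + vol$voxel_size[2] / 2)
    stop_qa("invalid_roi", "ROI extends outside the image")
  vol$ct[, , slice][d2 <= rad^2]
}

#' Mean and standard deviation of CT numbers in a circular ROI
#'
#' Statistics over the voxels whose centres fall inside the circle on the
#' given slice; the standard deviation uses the n−1 denominator.
#'
#' @param x A `volume_image` or `qa_volume`.
#' @param center Numeric `(x, y)` ROI centre (mm).
#' @param diameter ROI diameter (mm); the conventional 6 mm by default.
#' @param slice Slice index.
#' @param min_voxels Minimum voxel count below which an error is raised.
#' @param phantom Optional `phantom_definition`.
#' @return List with `mean` (HU), `sd` (HU) and `n_voxels`.
#' @export
roi_stats <- function(x, center, diameter = 6, slice = 1, min_voxels = 5,
                      phantom = NULL) {
  vol <- as_qa_volume(x, phantom)
  v <- roi_values(vol, center, diameter, slice)
  if (length(v) < min_voxels)
    stop_qa("invalid_roi", "ROI contains %d voxels (< %d)", length(v), min_voxels)
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0, n_voxels = length(v))
}

# ROI mean / sd averaged over several slices (independent noise per slice)
roi_multi <- function(vol, center, diameter, slices, min_voxels = 5) {
  st <- lapply(slices, function(s)
    roi_stats(vol, center, diameter, s, min_voxels = min_voxels))
  list(mean = mean(vapply(st, `[[`, 0, "mean")),
       sd = mean(vapply(st, `[[`, 0, "sd")),
       n_voxels = st[[1]]$n_voxels)
}

uniformity_roi_centers <- function(center, radius, peripheral_frac) {
  rp <- radius * peripheral_frac
  ang <- c(0, 90, 180, 270) * pi / 180
  list(center = center,
       peripheral = lapply(ang, function(a)
         center + rp * c(cos(a), sin(a))))
}

#' Image noise on the CTP486 uniformity module
#'
#' The mean of the CT-number standard deviations in five 6 mm ROIs: one at
#' the phantom centre and four at peripheral positions (0/90/180/270
#' degrees, at `peripheral_frac` of the phantom radius).
#'
#' @param x A `volume_image` or `qa_volume`.
#' @param phantom Optional `phantom_definition` (taken from the volume if
#'   rendered by this package).
#' @param slice Slice index; default the central CTP486 slice.
#' @param peripheral_frac Peripheral ROI radius as a fraction of the
#'   phantom radius.
#' @param roi_diameter ROI diameter (mm).
#' @param n_slices Number of adjacent slices to average over.
#' @return Noise (HU, scalar) with the five per-ROI standard deviations
#'   attached as attribute `"roi_sd"`.
#' @export
measure_noise <- function(x, phantom = NULL, slice = NULL,
                          peripheral_frac = 0.7, roi_diameter = 6,
                          n_slices = 1) {
  vol <- resolve_vol(x, phantom)
  slices <- if (is.null(slice)) module_slices(vol, "CTP486", n_slices) else slice
  ctr <- locate_center(vol, slices[1])
  rois <- uniformity_roi_centers(ctr, vol$phantom$diameter_mm / 2, peripheral_frac)
  all_rois <- c(list(rois$center), rois$peripheral)
  sds <- vapply(all_rois, function(cc)
    roi_multi(vol, cc, roi_diameter, slices)$sd, 0)
  structure(mean(sds), roi_sd = sds)
}

#' Contrast-to-noise ratio on the CTP404 module
#'
#' `CNR = (S(insert ROI) - S(background ROI)) / sd(background ROI)`, by
#' default on the polystyrene insert (the lowest-contrast material, −35 HU
#' nominal), so the CNR of an ideal scan is negative.
#'
#' @param x A `volume_image` or `qa_volume`.
#' @param phantom Optional `phantom_definition`.
#' @param slice Slice index; default the central CTP404 slice.
#' @param insert Insert material used for the contrast ROI.
#' @param roi_diameter ROI diameter (mm).
#' @param bg_radius Radial position (mm) of the background ROI, placed at
#'   the angle midway between the first two inserts.
#' @param n_slices Number of adjacent slices to average over.
#' @return CNR (unitless scalar) with insert/background means and the
#'   background sd attached as attributes.
#' @export
measure_cnr <- function(x, phantom = NULL, slice = NULL,
                        insert = "polystyrene", roi_diameter = 6,
                        bg_radius = 30, n_slices = 1) {
  vol <- resolve_vol(x, phantom)
  slices <- if (is.null(slice)) module_slices(vol, "CTP404", n_slices) else slice
  ctr <- locate_center(vol, slices[1])
  mod <- phantom_module(vol$phantom, "CTP404")
  ins <- mod$inserts[mod$inserts$material == insert, ]
  if (nrow(ins) != 1)
    stop_qa("configuration_error", "no insert of material '%s'", insert)
  th <- ins$angle_deg * pi / 180
  ins_center <- ctr + ins$radius_mm * c(cos(th), sin(th))
  bg_th <- mean(mod$inserts$angle_deg[1:2]) * pi / 180
  bg_center <- ctr + bg_radius * c(cos(bg_th), sin(bg_th))
  s_roi <- roi_multi(vol, ins_center, roi_diameter, slices)
  s_bg <- roi_multi(vol, bg_center, roi_diameter, slices)
  if (s_bg$sd == 0)
    stop_qa("undefined_cnr", "background standard deviation is zero")
  structure((s_roi$mean - s_bg$mean) / s_bg$sd,
            insert_mean = s_roi$mean, bg_mean = s_bg$mean, bg_sd = s_bg$sd)
}

#' Uniformity index on the CTP486 module
#'
#' `UI = S(peripheral ROIs) - S(centre ROI)` (HU).  Four peripheral 6 mm
#' ROIs are measured at 0/90/180/270 degrees and aggregated by their mean
#' (or, with `aggregate = "max"`, the single ROI deviating most from the
#' centre).  A positive UI beyond `tolerance` is classified as a cupping
#' artifact, a negative one as capping.
#'
#' @inheritParams measure_noise
#' @param tolerance |UI| (HU) below which the image is called uniform.
#' @param aggregate `"mean"` (default) or `"max"` peripheral aggregation.
#' @return A `uniformity_result` list: `ui`, `center_mean`,
#'   `peripheral_means`, `classification`.
#' @export
measure_uniformity <- function(x, phantom = NULL, slice = NULL,
                               peripheral_frac = 0.7, roi_diameter = 6,
                               tolerance = 5, aggregate = c("mean", "max"),
                               n_slices = 1) {
  aggregate <- match.arg(aggregate)
  vol <- resolve_vol(x, phantom)
  slices <- if (is.null(slice)) module_slices(vol, "CTP486", n_slices) else slice
  ctr <- locate_center(vol, slices[1])
  rois <- uniformity_roi_centers(ctr, vol$phantom$diameter_mm / 2, peripheral_frac)
  cm <- roi_multi(vol, rois$center, roi_diameter, slices)$mean
  pm <- vapply(rois$peripheral, function(cc)
    roi_multi(vol, cc, roi_diameter, slices)$mean, 0)
  ui <- if (aggregate == "mean") mean(pm) - cm else pm[which.max(abs(pm - cm))] - cm
  structure(list(ui = ui, center_mean = cm, peripheral_means = pm,
                 classification = if (ui > tolerance) "cupping"
                                  else if (ui < -tolerance) "capping"
                                  else "uniform"),
            class = "uniformity_result")
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("UI = %.2f HU (%s); centre %.2f HU, periphery %s HU\n",
              x$ui, x$classification, x$center_mean,
              paste(sprintf("%.2f", x$peripheral_means), collapse = "/")))
  invisible(x)
}

#' High-contrast resolution on the CTP528 line-pair module
#'
#' Automated replacement for the visual bar-pattern reading.  For each
#' 1..21 lp/cm group the voxels inside the group are classified bar/gap by
#' the nominal pattern and the modulation
#' `(mean(bar voxels) - mean(gap voxels)) / nominal contrast` is computed.
#' A group is resolvable when all of the following hold: its frequency
#' does not exceed the rounded Nyquist bound of the pixel pitch (a sampled
#' image cannot represent faster patterns); the modulation reaches
#' `threshold`; the bar-gap difference exceeds twice the image noise; and
#' the dominant DFT frequency of the group's pixel-pitch-binned profile is
#' within `freq_tol` of nominal (this rejects aliased patterns reproduced
#' at the wrong frequency).  The reported maximum stops at the first
#' unresolvable group.
#'
#' @inheritParams measure_noise
#' @param threshold Minimum modulation for a resolvable group.
#' @param noise Image noise (HU) for the 2-sigma contrast rule; estimated
#'   from a background ROI at the module centre when `NULL`.
#' @param freq_tol Relative tolerance of the dominant-frequency check.
#' @return A `resolution_result` list: `max_resolvable` (lp/cm) and
#'   `per_group` data.frame (frequency, modulation, dominant frequency,
#'   resolvable).
#' @export
measure_resolution <- function(x, phantom = NULL, slice = NULL,
                               threshold = 0.2, noise = NULL,
                               freq_tol = 0.3) {
  vol <- resolve_vol(x, phantom)
  sl <- if (is.null(slice)) module_slices(vol, "CTP528", 1) else slice[1]
  ctr <- locate_center(vol, sl)
  mod <- phantom_module(vol$phantom, "CTP528")
  g <- mod$line_pair_groups
  if (is.null(g)) stop_qa("configuration_error", "phantom has no line-pair layout")
  if (is.null(noise))
    noise <- roi_stats(vol, ctr, diameter = 20, slice = sl, min_voxels = 5)$sd
  pitch <- vol$voxel_size[1]
  nyq <- nyquist_bound(pitch)$rounded
  pc <- plane_coords(vol)
  img <- vol$ct[, , sl]
  X <- matrix(pc$x - ctr[1], length(pc$y), length(pc$x), byrow = TRUE)
  Y <- matrix(pc$y - ctr[2], length(pc$y), length(pc$x))
  res <- data.frame(freq_lp_cm = g$freq_lp_cm, modulation = NA_real_,
                    dominant_freq = NA_real_, resolvable = FALSE)
  for (i in seq_len(nrow(g))) {
    th <- g$angle_deg[i] * pi / 180
    u <- -X * sin(th) + Y * cos(th)
    w <- X * cos(th) + Y * sin(th) - g$radius_mm[i]
    half <- g$width_mm[i] / 2
    inreg <- abs(w) <= g$bar_length_mm[i] / 2 & u >= -half & u < half
    if (!any(inreg)) next
    per <- 10 / g$freq_lp_cm[i]
    barm <- ((u + half) %% per) < g$bar_width_mm[i]
    vb <- img[inreg & barm]; vg <- img[inreg & !barm]
    if (length(vb) == 0 || length(vg) == 0) next
    modl <- (mean(vb) - mean(vg)) / g$contrast_hu[i]
    res$modulation[i] <- modl
    # pixel-pitch-binned profile along the pattern direction
    brk <- seq(-half, half, by = pitch)
    if (length(brk) >= 5) {
      bin <- findInterval(u[inreg], brk, rightmost.closed = TRUE)
      keep <- bin >= 1 & bin < length(brk)
      prof <- tapply(img[inreg][keep], bin[keep], mean)
      m <- length(prof)
      sp <- Mod(fft(prof - mean(prof)))[seq_len(floor(m / 2) + 1)]
      fdom <- which.max(sp[-1]) / (m * pitch) * 10
      res$dominant_freq[i] <- fdom
    } else fdom <- g$freq_lp_cm[i]  # too few bins to test; rely on Nyquist cap
    res$resolvable[i] <- g$freq_lp_cm[i] <= nyq &&
      modl >= threshold &&
      (mean(vb) - mean(vg)) > 2 * noise &&
      abs(fdom - g$freq_lp_cm[i]) / g$freq_lp_cm[i] <= freq_tol
  }
  first_fail <- match(FALSE, res$resolvable, nomatch = nrow(res) + 1L)
  structure(list(max_resolvable = as.integer(first_fail - 1L),
                 per_group = res, noise = noise),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("max resolvable: %d lp/cm\n", x$max_resolvable))
  invisible(x)
}

#' Low-contrast detectability on the CTP515 module
#'
#' Automated replacement for counting visible discs.  Each supra-slice
#' disc gets a Rose-criterion detectability index
#' `d = |S(disc ROI) - S(local background ROI)| * sqrt(n_voxels) / noise`;
#' the disc is called visible when `d >= k_rose`.  The local background
#' ROI sits at the same radius, offset midway towards the neighbouring
#' disc.
#'
#' @inheritParams measure_noise
#' @param noise Image noise (HU); estimated from a background ROI at the
#'   module centre when `NULL`.
#' @param k_rose Rose visibility threshold.
#' @param roi_frac Disc-ROI diameter as a fraction of the disc diameter
#'   (capped at 6 mm).
#' @return A `low_contrast_result` list: `visible_counts` per contrast
#'   level and `per_disc` data.frame with the detectability indices.
#' @export
measure_low_contrast <- function(x, phantom = NULL, noise = NULL, slice = NULL,
                                 k_rose = 3, roi_frac = 0.7, n_slices = 1) {
  vol <- resolve_vol(x, phantom)
  slices <- if (is.null(slice)) module_slices(vol, "CTP515", n_slices) else slice
  ctr <- locate_center(vol, slices[1])
  mod <- phantom_module(vol$phantom, "CTP515")
  d <- mod$discs
  if (is.null(d)) stop_qa("configuration_error", "phantom has no low-contrast layout")
  if (is.null(noise))
    noise <- roi_stats(vol, ctr, diameter = 20, slice = slices[1], min_voxels = 5)$sd
  if (noise <= 0) noise <- .Machine$double.eps
  per <- d
  # floor at 1.5x pixel pitch so even the 2 mm disc ROI holds >= 1 voxel centre
  per$roi_diameter <- pmin(6, pmax(roi_frac * d$diameter_mm,
                                   1.5 * vol$voxel_size[1]))
  per$d_index <- NA_real_
  for (i in seq_len(nrow(d))) {
    th <- d$angle_deg[i] * pi / 180
    cc <- ctr + d$radius_mm[i] * c(cos(th), sin(th))
    thb <- (d$angle_deg[i] + 20) * pi / 180
    cb <- ctr + d$radius_mm[i] * c(cos(thb), sin(thb))
    sd_roi <- roi_multi(vol, cc, per$roi_diameter[i], slices, min_voxels = 1)
    sb_roi <- roi_multi(vol, cb, 6, slices, min_voxels = 5)
    per$d_index[i] <- abs(sd_roi$mean - sb_roi$mean) *
      sqrt(sd_roi$n_voxels * length(slices)) / noise
  }
  per$visible <- per$d_index >= k_rose
  counts <- tapply(per$visible, per$contrast_pct, sum)
  counts <- counts[order(as.numeric(names(counts)), decreasing = TRUE)]
  structure(list(visible_counts = counts, per_disc = per, noise = noise,
                 k_rose = k_rose),
            class = "low_contrast_result")
}

#' @export
print.low_contrast_result <- function(x, ...) {
  cat("visible discs:",
      paste(sprintf("%s%%: %d/9", names(x$visible_counts), x$visible_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pixel-value stability of the CTP404 inserts across an mAs series
#'
#' For each insert material, the ROI mean CT number at every total-mAs
#' setting and the spread (max − min, HU) across the series.  A stable
#' system keeps every insert within a 40 HU range; a drifting detector
#' response shows up as ranges of hundreds of HU.
#'
#' @param scans List of scans, each a list with elements `volume` (a
#'   `volume_image` or `qa_volume`) and `total_mas`, as returned by
#'   [simulate_mas_series()].
#' @param phantom Optional `phantom_definition`.
#' @param roi_diameter ROI diameter (mm).
#' @param n_slices Number of adjacent slices to average over.
#' @return A `stability_result` list: `curves` (data.frame material,
#'   total_mas, mean_hu, sorted by mAs) and `ranges` (named HU vector).
#' @export
pixel_stability <- function(scans, phantom = NULL, roi_diameter = 6,
                            n_slices = 1) {
  if (length(scans) < 2)
    stop_qa("incompatible_series", "need at least 2 scans for a stability study")
  vols <- lapply(scans, function(s) resolve_vol(s$volume, phantom))
  mas <- vapply(scans, function(s) s$total_mas, 0)
  dims <- vapply(vols, function(v) dim(v$ct), c(0, 0, 0))
  vx <- vapply(vols, function(v) v$voxel_size, c(0, 0, 0))
  if (any(dims != dims[, 1]) || any(vx != vx[, 1]))
    stop_qa("incompatible_series", "scans have mismatched geometry")
  ord <- order(mas)
  vols <- vols[ord]; mas <- mas[ord]
  mod <- phantom_module(vols[[1]]$phantom, "CTP404")
  rows <- list()
  for (si in seq_along(vols)) {
    vol <- vols[[si]]
    slices <- module_slices(vol, "CTP404", n_slices)
    ctr <- locate_center(vol, slices[1])
    for (i in seq_len(nrow(mod$inserts))) {
      ins <- mod$inserts[i, ]
      th <- ins$angle_deg * pi / 180
      cc <- ctr + ins$radius_mm * c(cos(th), sin(th))
      rows[[length(rows) + 1]] <- data.frame(
        material = ins$material, total_mas = mas[si],
        mean_hu = roi_multi(vol, cc, roi_diameter, slices)$mean)
    }
  }
  curves <- do.call(rbind, rows)
  curves <- curves[order(curves$material, curves$total_mas), ]
  rownames(curves) <- NULL
  ranges <- tapply(curves$mean_hu, curves$material, function(v) max(v) - min(v))
  structure(list(curves = curves, ranges = c(ranges)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("per-insert range (max-min, HU):\n")
  print(round(x$ranges, 2))
  invisible(x)
}
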