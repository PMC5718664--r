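# Synthetic CATPHAN CBCT generator.  A noiseless phantom volume is rendered
# by area-weighted supersampling, then degraded by a fixed pipeline:
# radial uniformity artifact -> mAs-dependent pixel drift -> in-plane
# Gaussian blur -> mAs-dependent Gaussian noise -> integer encoding.
# Noise is always last so it stays uncorrelated between voxels.

#' Artifact model parameters for the synthetic scan generator
#'
#' @param uniformity_amplitude Radial artifact amplitude A (HU) added as
#'   `A * (r/R)^exponent` inside the phantom; positive A raises the
#'   periphery over the centre (cupping), negative A the reverse (capping).
#' @param radial_exponent Radial profile exponent p (default 2).
#' @param noise_coefficient k (HU sqrt(mAs)); the noise standard deviation
#'   at total output `mAs` is `k / sqrt(mAs)`.
#' @param psf_fwhm In-plane Gaussian blur FWHM (mm); 0 disables blur.
#' @param drift Named list mapping material class to `c(offset, slope)`:
#'   the class gains `offset + slope * log2(mAs / reference mAs)` HU.  The
#'   name `"*"` applies to every in-phantom class.  An empty list is the
#'   all-zero (no drift) map.
#' @param seed Integer RNG seed for the noise stage.
#' @return An object of class `artifact_params`.
#' @export
artifact_params <- function(uniformity_amplitude = 0, radial_exponent = 2,
                            noise_coefficient = 0, psf_fwhm = 0,
                            drift = list(), seed = NULL) {
  if (noise_coefficient < 0 || psf_fwhm < 0)
    stop_qa("configuration_error", "noise_coefficient and psf_fwhm must be >= 0")
  structure(list(uniformity_amplitude = uniformity_amplitude,
                 radial_exponent = radial_exponent,
                 noise_coefficient = noise_coefficient,
                 psf_fwhm = psf_fwhm, drift = drift, seed = seed),
            class = "artifact_params")
}

# Protocol-average uniformity indices (HU) the default presets emulate,
# small phantom / large phantom.
UI_PRESETS <- list(
  "obi-full-fan" = c(-20.78, -20.78),
  "obi-half-fan" = c(11.58, 26.72),
  "xvi-head-neck" = c(10.38, NA),
  "xvi-prostate" = c(-46.12, -27.70),
  "xvi-pelvis" = c(-30.41, -39.39),
  "xvi-chest" = c(-33.47, -288.67))

#' Default artifact presets emulating a scan protocol
#'
#' Presets are calibrated so that (i) noise at the protocol's lowest total
#' mAs is 25 HU, (ii) the uniformity index measured with peripheral ROIs
#' at 70% radius reproduces the protocol-average UI (the amplitude is
#' UI / 0.49 since UI = A (r_p/R)^2), and (iii) XVI scans drift by
#' -160 HU per doubling of mAs (> 300 HU across each protocol's 4x mAs
#' range) while OBI scans do not drift.  XVI images are smoother than OBI
#' (heavier post-reconstruction filtering), reflected in a wider PSF.
#'
#' @param protocol A `scan_protocol` or protocol name.
#' @param phantom_size `"small"` (bare phantom) or `"large"` (with body
#'   annulus).
#' @param seed RNG seed for the noise stage.
#' @return An `artifact_params` object.
#' @export
default_artifacts <- function(protocol, phantom_size = c("small", "large"),
                              seed = NULL) {
  if (is.character(protocol)) protocol <- get_protocol(protocol)
  phantom_size <- match.arg(phantom_size)
  ui <- UI_PRESETS[[protocol$name]]
  ui <- if (phantom_size == "large") ui[2] else ui[1]
  if (is.na(ui)) ui <- 0
  artifact_params(
    uniformity_amplitude = ui / 0.49,
    radial_exponent = 2,
    noise_coefficient = 25 * sqrt(min(protocol_total_mas(protocol))),
    psf_fwhm = if (protocol$system == "XVI") 1.5 else 0.8,
    drift = if (protocol$system == "XVI") list("*" = c(0, -160)) else list(),
    seed = seed)
}

LABEL_LEVELS <- c("exterior", "background", "annulus", "bar", "disc",
                  catphan_materials()$name[catphan_materials()$name != "water"])

# material value and label at each grid point of one module's plane
plane_fields <- function(phantom, module, X, Y, labels = FALSE) {
  R <- phantom$diameter_mm / 2
  r2 <- X^2 + Y^2
  v <- matrix(-1000, nrow(X), ncol(X))
  lab <- if (labels) matrix(match("exterior", LABEL_LEVELS), nrow(X), ncol(X))
  if (!is.na(phantom$annulus_diameter_mm)) {
    m <- r2 <= (phantom$annulus_diameter_mm / 2)^2
    v[m] <- phantom$annulus_ct
    if (labels) lab[m] <- match("annulus", LABEL_LEVELS)
  }
  m <- r2 <= R^2
  v[m] <- phantom$background_ct
  if (labels) lab[m] <- match("background", LABEL_LEVELS)
  if (module$kind == "CTP404") {
    for (i in seq_len(nrow(module$inserts))) {
      ins <- module$inserts[i, ]
      th <- ins$angle_deg * pi / 180
      cx <- ins$radius_mm * cos(th); cy <- ins$radius_mm * sin(th)
      m <- (X - cx)^2 + (Y - cy)^2 <= (ins$diameter_mm / 2)^2
      v[m] <- ins$nominal_ct
      if (labels) lab[m] <- match(ins$material, LABEL_LEVELS)
    }
  } else if (module$kind == "CTP528") {
    g <- module$line_pair_groups
    for (i in seq_len(nrow(g))) {
      th <- g$angle_deg[i] * pi / 180
      u <- -X * sin(th) + Y * cos(th)
      w <- X * cos(th) + Y * sin(th) - g$radius_mm[i]
      per <- 10 / g$freq_lp_cm[i]
      inreg <- abs(w) <= g$bar_length_mm[i] / 2 &
        u >= -g$width_mm[i] / 2 & u < g$width_mm[i] / 2
      barm <- inreg & ((u + g$width_mm[i] / 2) %% per) < g$bar_width_mm[i]
      v[barm] <- phantom$background_ct + g$contrast_hu[i]
      if (labels) lab[barm] <- match("bar", LABEL_LEVELS)
    }
  } else if (module$kind == "CTP515") {
    d <- module$discs
    for (i in seq_len(nrow(d))) {
      th <- d$angle_deg[i] * pi / 180
      cx <- d$radius_mm[i] * cos(th); cy <- d$radius_mm[i] * sin(th)
      m <- (X - cx)^2 + (Y - cy)^2 <= (d$diameter_mm[i] / 2)^2
      v[m] <- phantom$background_ct + d$contrast_hu[i]
      if (labels) lab[m] <- match("disc", LABEL_LEVELS)
    }
  }
  list(values = v, labels = lab)
}

# average an (n*ss) x (n*ss) matrix over ss x ss blocks
block_mean <- function(v, n, ss) {
  if (ss == 1) return(v)
  a <- colMeans(array(v, c(ss, n, ss * n)))        # -> (n, ss*n) over rows
  a <- array(a, c(n, ss, n))
  colMeans(aperm(a, c(2, 1, 3)))                   # average over col sub-pixels
}

#' Render a noiseless CATPHAN volume
#'
#' Every voxel carries the nominal CT number of the material at its
#' location, with partial-volume averaging by `supersample`-fold
#' area-weighted supersampling per axis; air (−1000 HU) outside the
#' phantom.  Slices are grouped per module, centred on each module's
#' axial offset.  The result carries a voxel-centre material-label array
#' used by the drift model.
#'
#' @param phantom A `phantom_definition`.
#' @param voxel_size Numeric triple (x, y, z) in mm.
#' @param slices_per_module Number of slices rendered per module.
#' @param fov_mm In-plane field of view (mm); default covers the phantom
#'   (and annulus) with a 20 mm margin.
#' @param supersample Supersampling factor per in-plane axis (>= 1;
#'   4 or more recommended).
#' @return A `qa_volume` of CT numbers (HU) with labels and the phantom
#'   attached.
#' @export
render_ideal_volume <- function(phantom, voxel_size = c(1, 1, 1),
                                slices_per_module = 5, fov_mm = NULL,
                                supersample = 4) {
  stopifnot(inherits(phantom, "phantom_definition"))
  if (any(voxel_size <= 0)) stop_qa("invalid_argument", "voxel_size must be positive")
  if (voxel_size[1] != voxel_size[2])
    stop_qa("invalid_argument", "in-plane voxels must be square")
  if (!is.null(phantom_module(phantom, "CTP515")) &&
      voxel_size[1] > min(ctp515_layout()$discs$diameter_mm))
    warning("voxel size exceeds the smallest low-contrast disc; targets unresolvable",
            call. = FALSE)
  dx <- voxel_size[1]; dz <- voxel_size[3]
  fov <- fov_mm %||% (2 * phantom_outer_radius(phantom) + 20)
  n <- as.integer(ceiling(fov / dx))
  ss <- as.integer(supersample)
  N <- n * ss
  step <- dx / ss
  cs <- (seq_len(N) - (N + 1) / 2) * step
  Xs <- matrix(cs, N, N, byrow = TRUE)   # x along columns
  Ys <- matrix(cs, N, N)                 # y along rows
  cv <- (seq_len(n) - (n + 1) / 2) * dx
  Xv <- matrix(cv, n, n, byrow = TRUE)
  Yv <- matrix(cv, n, n)
  spm <- as.integer(slices_per_module)
  zoff <- (seq_len(spm) - (spm + 1) / 2) * dz
  nz <- spm * length(phantom$modules)
  ct <- array(NA_real_, c(n, n, nz))
  labels <- array(NA_integer_, c(n, n, nz))
  slice_z <- numeric(nz)
  for (mi in seq_along(phantom$modules)) {
    mod <- phantom$modules[[mi]]
    tmpl <- block_mean(plane_fields(phantom, mod, Xs, Ys)$values, n, ss)
    lab <- plane_fields(phantom, mod, Xv, Yv, labels = TRUE)$labels
    idx <- (mi - 1) * spm + seq_len(spm)
    for (k in seq_len(spm)) {
      ct[, , idx[k]] <- tmpl
      labels[, , idx[k]] <- lab
    }
    slice_z[idx] <- mod$z_offset + zoff
  }
  qa_volume(ct, voxel_size = voxel_size, origin = c(cv[1], cv[1]),
            slice_z = slice_z, labels = labels, label_levels = LABEL_LEVELS,
            phantom = phantom)
}

#' Add a radial uniformity (cupping/capping) artifact
#'
#' In-phantom voxels at in-plane radius `r` gain `A * (r/R)^p` HU, where
#' `R` is the phantom's outer radius (annulus included).  Air outside the
#' phantom is unchanged.  Positive `A` makes the periphery brighter than
#' the centre (cupping, positive uniformity index); negative `A` the
#' opposite (capping).
#'
#' @param vol A `qa_volume` rendered by [render_ideal_volume()].
#' @param amplitude Artifact amplitude A (HU).
#' @param exponent Radial exponent p.
#' @return The modified `qa_volume`.
#' @export
apply_uniformity_artifact <- function(vol, amplitude, exponent = 2) {
  stopifnot(inherits(vol, "qa_volume"))
  if (amplitude == 0) return(vol)
  R <- phantom_outer_radius(vol$phantom)
  pc <- plane_coords(vol)
  r <- sqrt(outer(pc$y^2, pc$x^2, `+`))
  add <- amplitude * (r / R)^exponent
  add[r > R] <- 0
  vol$ct <- vol$ct + as.vector(add)   # recycled across slices
  vol
}

#' Add mAs-dependent pixel-value drift per material class
#'
#' Each in-phantom material class gains
#' `offset + slope * log2(total_mas / reference_mas)` HU, the simplest
#' monotone model of detector-response drift with tube output.
#'
#' @param vol A `qa_volume` with a label array.
#' @param total_mas Total mAs of the emulated scan.
#' @param drift Drift map as in [artifact_params()]; empty list = no drift.
#' @param reference_mas Total mAs at which the drift offset applies.
#' @return The modified `qa_volume`.
#' @export
apply_drift <- function(vol, total_mas, drift, reference_mas) {
  stopifnot(inherits(vol, "qa_volume"))
  if (length(drift) == 0) return(vol)
  if (is.null(vol$labels)) stop_qa("configuration_error", "volume carries no material labels")
  lg <- log2(total_mas / reference_mas)
  present <- setdiff(unique(as.vector(vol$labels)), match("exterior", LABEL_LEVELS))
  for (li in present) {
    cls <- vol$label_levels[li]
    par <- drift[[cls]] %||% drift[["*"]]
    if (is.null(par))
      stop_qa("configuration_error", "no drift entry for material class '%s'", cls)
    vol$ct[vol$labels == li] <- vol$ct[vol$labels == li] + par[1] + par[2] * lg
  }
  vol
}

#' Apply isotropic in-plane Gaussian blur
#'
#' Emulates the resolution loss of reconstruction and post-filtering with
#' a Gaussian point-spread function of the stated FWHM.
#'
#' @param vol A `qa_volume`.
#' @param psf_fwhm PSF full width at half maximum (mm); 0 is the identity.
#' @return The modified `qa_volume`.
#' @export
apply_blur <- function(vol, psf_fwhm) {
  stopifnot(inherits(vol, "qa_volume"), psf_fwhm >= 0)
  if (psf_fwhm == 0) return(vol)
  sigma_px <- psf_fwhm / (2 * sqrt(2 * log(2))) / vol$voxel_size[1]
  for (k in seq_len(dim(vol$ct)[3]))
    vol$ct[, , k] <- EBImage::gblur(vol$ct[, , k], sigma = sigma_px)
  vol
}

#' Add mAs-dependent Gaussian noise
#'
#' Adds zero-mean white Gaussian noise with standard deviation
#' `k / sqrt(total_mas)` HU, emulating the asymptotic decrease of
#' reconstructed noise with tube output.
#'
#' @param vol A `qa_volume`.
#' @param total_mas Total mAs of the emulated scan (> 0).
#' @param k Noise coefficient (HU sqrt(mAs)); 0 is the identity.
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return The modified `qa_volume`.
#' @export
apply_noise <- function(vol, total_mas, k, seed = NULL) {
  stopifnot(inherits(vol, "qa_volume"))
  if (!is_number(total_mas) || total_mas <= 0)
    stop_qa("invalid_argument", "total_mas must be positive")
  if (k == 0) return(vol)
  sigma <- k / sqrt(total_mas)
  vol$ct <- vol$ct + local_seed(seed, rnorm(length(vol$ct), 0, sigma))
  vol
}

#' Configuration for one simulated scan
#'
#' @param protocol A `scan_protocol` or protocol name.
#' @param setting Index (1-based) into the protocol's mAs settings.
#' @param phantom A `phantom_definition`.
#' @param artifacts An `artifact_params`; default [default_artifacts()].
#' @param slices_per_module Slices rendered per module.
#' @param out_dir Optional directory for the DICOM series + manifest.
#' @param seed RNG seed for the noise stage.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(protocol, setting = 1, phantom = catphan_phantom(),
                              artifacts = NULL, slices_per_module = 5,
                              out_dir = NULL, seed = NULL) {
  if (is.character(protocol)) protocol <- get_protocol(protocol)
  if (setting < 1 || setting > nrow(protocol$settings))
    stop_qa("invalid_protocol", "setting %d out of range for '%s' (1..%d)",
            setting, protocol$name, nrow(protocol$settings))
  phantom_size <- if (is.na(phantom$annulus_diameter_mm)) "small" else "large"
  artifacts <- artifacts %||% default_artifacts(protocol, phantom_size, seed = seed)
  structure(list(protocol = protocol, setting = as.integer(setting),
                 phantom = phantom, artifacts = artifacts,
                 slices_per_module = as.integer(slices_per_module),
                 out_dir = out_dir, seed = seed %||% artifacts$seed),
            class = "simulation_config")
}

sim_manifest <- function(config, total_mas, sigma, intercept) {
  list(tool = "catphanqa",
       version = as.character(utils::packageVersion("catphanqa")),
       protocol = config$protocol$name,
       system = config$protocol$system,
       setting = config$setting,
       total_mas = total_mas,
       seed = config$seed,
       rescale_intercept = intercept,
       phantom = list(modules = vapply(config$phantom$modules, `[[`, "", "kind"),
                      annulus = !is.na(config$phantom$annulus_diameter_mm)),
       truth = list(uniformity_amplitude = config$artifacts$uniformity_amplitude,
                    radial_exponent = config$artifacts$radial_exponent,
                    noise_coefficient = config$artifacts$noise_coefficient,
                    noise_sigma = sigma,
                    psf_fwhm = config$artifacts$psf_fwhm,
                    drift = config$artifacts$drift))
}

#' Simulate one CBCT scan of the CATPHAN phantom
#'
#' Runs the full pipeline render -> uniformity artifact -> drift -> blur
#' -> noise -> integer encoding, and optionally writes the DICOM series
#' with a JSON sidecar manifest recording the ground-truth parameters.
#' The rescale intercept is −510 for XVI-like scans and −1000 for
#' OBI-like scans, with slope 1.
#'
#' @param config A `simulation_config`.
#' @return A `volume_image`; if `config$out_dir` is set, the series and
#'   `manifest.json` are written there and the manifest is attached as
#'   attribute `"manifest"`.
#' @export
simulate_scan <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$protocol
  a <- config$artifacts
  mas <- protocol_total_mas(p, config$setting)
  ref <- min(protocol_total_mas(p))
  vol <- render_ideal_volume(config$phantom, p$voxel_size_mm,
                             config$slices_per_module)
  vol <- apply_uniformity_artifact(vol, a$uniformity_amplitude, a$radial_exponent)
  vol <- apply_drift(vol, mas, a$drift, ref)
  vol <- apply_blur(vol, a$psf_fwhm)
  vol <- apply_noise(vol, mas, a$noise_coefficient, config$seed)
  intercept <- if (p$system == "XVI") -510 else -1000
  sigma <- if (a$noise_coefficient > 0) a$noise_coefficient / sqrt(mas) else 0
  img <- encode_volume(vol, rescale_intercept = intercept,
                       meta = list(protocol = p$name, setting = config$setting,
                                   total_mas = mas, seed = config$seed,
                                   kvp = p$kvp))
  manifest <- sim_manifest(config, mas, sigma, intercept)
  if (!is.null(config$out_dir)) {
    write_series(img, config$out_dir,
                 series_description = sprintf("%s setting %d", p$name, config$setting),
                 uid_seed = config$seed %||% 0L)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(img, "manifest") <- manifest
  img
}

#' Simulate a full mAs series under one protocol
#'
#' Renders the phantom once and emulates every requested mAs setting from
#' it (drift, blur and noise are per-setting; the noiseless render and the
#' uniformity artifact are shared), which is how a physical mAs series is
#' acquired: one phantom setup, several exposures.
#'
#' @param protocol A `scan_protocol` or protocol name.
#' @param phantom A `phantom_definition`.
#' @param artifacts An `artifact_params`; default [default_artifacts()].
#' @param settings Setting indices to simulate; default all.
#' @param slices_per_module Slices rendered per module.
#' @param seed Base RNG seed; setting `i` uses `seed + i`.
#' @param out_dir Optional directory; each setting is written to
#'   `setting_<i>/` plus a `series_manifest.csv` usable by
#'   [analyze_series()].
#' @return List with one element per setting: `list(volume, total_mas,
#'   setting, manifest)`.
#' @export
simulate_mas_series <- function(protocol, phantom = catphan_phantom(),
                                artifacts = NULL, settings = NULL,
                                slices_per_module = 5, seed = 1L,
                                out_dir = NULL) {
  if (is.character(protocol)) protocol <- get_protocol(protocol)
  phantom_size <- if (is.na(phantom$annulus_diameter_mm)) "small" else "large"
  a <- artifacts %||% default_artifacts(protocol, phantom_size)
  settings <- settings %||% seq_len(nrow(protocol$settings))
  all_mas <- protocol_total_mas(protocol)
  ref <- min(all_mas)
  base <- render_ideal_volume(phantom, protocol$voxel_size_mm, slices_per_module)
  base <- apply_uniformity_artifact(base, a$uniformity_amplitude, a$radial_exponent)
  static <- length(a$drift) == 0
  if (static) base_blurred <- apply_blur(base, a$psf_fwhm)
  intercept <- if (protocol$system == "XVI") -510 else -1000
  rows <- list()
  out <- vector("list", length(settings))
  for (j in seq_along(settings)) {
    i <- settings[j]
    mas <- all_mas[i]
    vol <- if (static) base_blurred
           else apply_blur(apply_drift(base, mas, a$drift, ref), a$psf_fwhm)
    vol <- apply_noise(vol, mas, a$noise_coefficient, seed + i)
    img <- encode_volume(vol, rescale_intercept = intercept,
                         meta = list(protocol = protocol$name, setting = i,
                                     total_mas = mas, seed = seed + i,
                                     kvp = protocol$kvp))
    cfg <- simulation_config(protocol, i, phantom, a,
                             slices_per_module, seed = seed + i)
    manifest <- sim_manifest(cfg, mas,
                             if (a$noise_coefficient > 0) a$noise_coefficient / sqrt(mas) else 0,
                             intercept)
    if (!is.null(out_dir)) {
      sdir <- file.path(out_dir, sprintf("setting_%d", i))
      write_series(img, sdir, sprintf("%s setting %d", protocol$name, i),
                   uid_seed = seed + i)
      jsonlite::write_json(manifest, file.path(sdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rows[[j]] <- data.frame(series_path = sprintf("setting_%d", i),
                              protocol = protocol$name, setting = i,
                              phantom_size = phantom_size, total_mas = mas)
    }
    attr(img, "manifest") <- manifest
    out[[j]] <- list(volume = img, total_mas = mas, setting = i,
                     manifest = manifest)
  }
  if (!is.null(out_dir))
    write.csv(do.call(rbind, rows), file.path(out_dir, "series_manifest.csv"),
              row.names = FALSE)
  out
}
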