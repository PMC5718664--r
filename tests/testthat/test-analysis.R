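test_that("phantom centre is located to sub-voxel accuracy", {
  vol <- fix_ctp486_1mm()
  ctr <- locate_center(vol, 1)
  expect_lt(max(abs(ctr)), 0.5)
  # shift the phantom by padding air on one side: centroid must follow
  n <- dim(vol$ct)[1]
  pad <- 10
  shifted <- array(-1000, c(n, n + pad, 1))
  shifted[, (pad + 1):(n + pad), 1] <- vol$ct[, , 1]
  sv <- qa_volume(shifted, voxel_size = vol$voxel_size,
                  origin = c(vol$origin[1] - pad, vol$origin[2]),
                  phantom = vol$phantom)
  ctr2 <- locate_center(sv, 1)
  expect_equal(unname(ctr2), unname(ctr), tolerance = 1e-6)
  expect_error(locate_center(flat_volume(-1000)), class = "phantom_not_found")
})

test_that("ROI statistics use voxel centres and the n-1 standard deviation", {
  vol <- flat_volume(42, n = 40)
  st <- roi_stats(vol, c(0, 0), 6, 1)
  expect_equal(st$mean, 42)
  expect_equal(st$sd, 0)
  expect_true(st$n_voxels >= 24 && st$n_voxels <= 32)
  # sweep ROI centre across sub-voxel offsets: count stays in [24, 32]
  for (off in seq(0, 0.9, by = 0.3)) {
    n <- roi_stats(vol, c(off, off / 2), 6, 1)$n_voxels
    expect_true(n >= 24 && n <= 32)
  }
  expect_error(roi_stats(vol, c(25, 0), 6, 1), class = "invalid_roi")
  expect_error(roi_stats(vol, c(0, 0), 0.5, 1), class = "invalid_roi")
  # Gaussian field: single-ROI sd near truth, and equal to a direct oracle
  g <- flat_volume(0, n = 40)
  set.seed(1)
  g$ct <- g$ct + rnorm(length(g$ct), 0, 20)
  st <- roi_stats(g, c(0, 0), 6, 1)
  pc <- catphanqa:::plane_coords(g)
  d2 <- outer(pc$y^2, pc$x^2, `+`)
  expect_equal(st$sd, sd(g$ct[, , 1][d2 <= 9]))
  expect_equal(st$sd, 20, tolerance = 0.15)
})

test_that("noise measurement averages five ROI standard deviations", {
  vol <- fix_ctp486_1mm()
  expect_equal(as.numeric(measure_noise(vol)), 0)
  n1 <- apply_noise(vol, 900, 600, seed = 11)     # sigma 20
  est1 <- measure_noise(n1, n_slices = 3)
  expect_equal(as.numeric(est1), 20, tolerance = 0.1)
  expect_length(attr(est1, "roi_sd"), 5)
  n2 <- apply_noise(vol, 900, 1200, seed = 12)    # sigma 40
  expect_equal(as.numeric(measure_noise(n2, n_slices = 3)) / as.numeric(est1),
               2, tolerance = 0.1)
})

test_that("CNR follows (S_ROI - S_BG) / sigma_BG on the polystyrene insert", {
  vol <- fix_ctp404_1mm()
  expect_error(measure_cnr(vol), class = "undefined_cnr")  # noiseless: sigma 0
  nv <- apply_noise(vol, 900, 300, seed = 21)              # sigma 10
  cnr <- measure_cnr(nv, n_slices = 3)
  expect_equal(as.numeric(cnr), -35 / 10, tolerance = 0.2)
  expect_lt(as.numeric(cnr), 0)   # polystyrene sits below water
  # |CNR| scales as 1/sigma
  nv2 <- apply_noise(vol, 900, 600, seed = 22)             # sigma 20
  cnr2 <- measure_cnr(nv2, n_slices = 3)
  expect_equal(as.numeric(cnr2) / as.numeric(cnr), 0.5, tolerance = 0.2)
  # invariance under a global additive offset
  sh <- nv
  sh$ct <- sh$ct + 150
  expect_equal(as.numeric(measure_cnr(sh, n_slices = 3)), as.numeric(cnr))
})

test_that("uniformity index matches the integrated artifact profile and its sign", {
  vol <- fix_ctp486_1mm()
  u0 <- measure_uniformity(vol)
  expect_equal(u0$ui, 0, tolerance = 0.1)
  expect_equal(u0$classification, "uniform")
  # oracle: UI = A * (0.7 R / R)^2 exactly (ROI curvature terms cancel)
  for (A in c(-300, -50, 20, 50)) {
    u <- measure_uniformity(apply_uniformity_artifact(vol, A, 2))
    expect_equal(u$ui, A * 0.49, tolerance = 0.01)
    expect_equal(u$classification, if (A > 0) "cupping" else "capping")
  }
  u <- measure_uniformity(apply_uniformity_artifact(vol, -300, 2))
  expect_lt(u$ui, -100)
  # invariance under a global additive offset
  ua <- apply_uniformity_artifact(vol, 50, 2)
  sh <- ua; sh$ct <- sh$ct + 300
  expect_equal(measure_uniformity(sh)$ui, measure_uniformity(ua)$ui)
  expect_length(u0$peripheral_means, 4)
})

test_that("resolution scorer is Nyquist-limited and degrades as expected", {
  vol <- fix_ideal_1mm()
  r <- measure_resolution(vol)
  expect_lte(r$max_resolvable, nyquist_bound(1)$rounded)
  expect_gte(r$max_resolvable, 4)
  expect_true(all(r$per_group$modulation[1:4] > 0.2))
  # a uniform phantom slice (no bars) resolves nothing
  u486 <- fix_ctp486_1mm()
  flat <- qa_volume(u486$ct[, , 1, drop = FALSE], voxel_size = u486$voxel_size,
                    origin = u486$origin,
                    slice_z = phantom_module(vol$phantom, "CTP528")$z_offset,
                    phantom = catphan_phantom("CTP528"))
  expect_equal(measure_resolution(flat)$max_resolvable, 0L)
  # first-failure rule: max equals the run of consecutive resolvable groups
  ok <- r$per_group$resolvable
  expect_equal(r$max_resolvable, match(FALSE, ok) - 1L)
})

test_that("low-contrast detectability follows the Rose criterion", {
  ph <- catphan_phantom("CTP515")
  vol <- render_ideal_volume(ph, c(1, 1, 1), slices_per_module = 3)
  lc0 <- measure_low_contrast(vol)          # noiseless: everything visible
  expect_true(all(lc0$visible_counts == 9))
  lc_inf <- measure_low_contrast(vol, noise = 1e6)
  expect_true(all(lc_inf$visible_counts == 0))
  # calibrated case: 10/5/3 HU discs, sigma = 15 HU, 1 mm pitch
  nv <- apply_noise(vol, 100, 150, seed = 31)
  lc <- measure_low_contrast(nv, noise = 15, n_slices = 3)
  counts <- lc$visible_counts                # ordered 1.0, 0.5, 0.3 %
  expect_equal(names(counts), c("1", "0.5", "0.3"))
  expect_true(all(diff(as.numeric(counts)) <= 0))
  per1 <- lc$per_disc[lc$per_disc$contrast_pct == 1, ]
  expect_true(per1$visible[per1$diameter_mm == 15])
  # larger discs are detected before smaller ones
  expect_gt(per1$d_index[per1$diameter_mm == 15],
            per1$d_index[per1$diameter_mm == 2])
  expect_true(all(lc$per_disc$d_index >= 0))
})

test_that("pixel stability reports per-insert curves and ranges across an mAs series", {
  vol <- fix_ctp404_1mm()
  img <- encode_volume(vol, -1000)
  # identical volumes: zero range
  st <- pixel_stability(list(list(volume = img, total_mas = 100),
                             list(volume = img, total_mas = 400)),
                        phantom = vol$phantom)
  expect_true(all(st$ranges == 0))
  expect_equal(nrow(st$curves), 14)
  expect_false(is.unsorted(st$curves$total_mas[st$curves$material == "teflon"]))
  expect_error(pixel_stability(list(list(volume = img, total_mas = 100)),
                               phantom = vol$phantom),
               class = "incompatible_series")
  # mismatched geometry is rejected
  other <- render_ideal_volume(catphan_phantom("CTP404"), c(2, 2, 2),
                               slices_per_module = 1)
  expect_error(pixel_stability(list(list(volume = img, total_mas = 100),
                                    list(volume = other, total_mas = 400)),
                               phantom = vol$phantom),
               class = "incompatible_series")
})

test_that("an XVI-like drift preset spans > 300 HU across the protocol's mAs range", {
  ph <- catphan_phantom("CTP404")
  arts <- artifact_params(noise_coefficient = 25 * sqrt(36.1),
                          drift = list("*" = c(0, -160)), psf_fwhm = 1.5)
  scans <- simulate_mas_series("xvi-head-neck", ph, arts,
                               slices_per_module = 3, seed = 41)
  st <- pixel_stability(scans, phantom = ph, n_slices = 3)
  # air saturates at the XVI encoding floor (-510 HU); other inserts drift
  drifting <- st$ranges[names(st$ranges) != "air"]
  expect_true(all(drifting > 300))
  for (m in names(drifting)) {
    cur <- st$curves[st$curves$material == m, ]
    expect_true(all(diff(cur$mean_hu) < 0))   # monotone decrease with mAs
  }
})
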