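test_that("ideal render reproduces nominal CT numbers with partial volume only at edges", {
  vol <- fix_ideal_1mm()
  pc <- catphanqa:::plane_coords(vol)
  r <- sqrt(outer(pc$y^2, pc$x^2, `+`))
  # CTP486 central slice: interior voxels exactly water (0 HU)
  s486 <- catphanqa:::module_slices(vol, "CTP486", 1)
  inner <- vol$ct[, , s486][r <= 95]
  expect_true(all(abs(inner) <= 0.02 * 1000))
  expect_equal(max(abs(inner)), 0)
  # outside the phantom is air
  expect_true(all(vol$ct[, , s486][r > 105] == -1000))
  # teflon insert interior mean is the Table value
  s404 <- catphanqa:::module_slices(vol, "CTP404", 1)
  ins <- phantom_module(vol$phantom, "CTP404")$inserts
  tef <- ins[ins$material == "teflon", ]
  th <- tef$angle_deg * pi / 180
  st <- roi_stats(vol, tef$radius_mm * c(cos(th), sin(th)), 6, s404)
  expect_equal(st$mean, 990)
  expect_equal(st$sd, 0)
  # 1% low-contrast discs sit 10 HU over background
  s515 <- catphanqa:::module_slices(vol, "CTP515", 1)
  d <- phantom_module(vol$phantom, "CTP515")$discs
  big <- d[d$contrast_pct == 1 & d$diameter_mm == 15, ]
  thb <- big$angle_deg * pi / 180
  stb <- roi_stats(vol, big$radius_mm * c(cos(thb), sin(thb)), 6, s515)
  expect_equal(stb$mean, 10)
})

test_that("uniformity artifact adds the closed-form radial profile inside the phantom", {
  vol <- fix_ctp486_1mm()
  expect_identical(apply_uniformity_artifact(vol, 0)$ct, vol$ct)
  u <- apply_uniformity_artifact(vol, 50, 2)
  delta <- u$ct[, , 1] - vol$ct[, , 1]
  pc <- catphanqa:::plane_coords(vol)
  r2 <- outer(pc$y^2, pc$x^2, `+`)
  inside <- r2 <= 100^2
  expect_equal(delta[inside], 50 * r2[inside] / 100^2)
  expect_true(all(delta[!inside] == 0))
  # ROI at r=0 vs r with (r/R)^2 = 0.5 differ by A/2
  rr <- 100 * sqrt(0.5)
  s0 <- roi_stats(u, c(0, 0), 6, 1)$mean
  s1 <- roi_stats(u, c(rr, 0), 6, 1)$mean
  expect_equal(s1 - s0, 25, tolerance = 0.01)
})

test_that("drift shifts material classes by offset + slope * log2(mAs ratio)", {
  vol <- fix_ctp404_1mm()
  expect_identical(apply_drift(vol, 400, list(), 100)$ct, vol$ct)
  dmap <- list("*" = c(0, -110))
  d4 <- apply_drift(vol, 400, dmap, 100)
  lab <- vol$labels
  bg <- lab == match("background", catphanqa:::LABEL_LEVELS)
  expect_equal(unique(d4$ct[bg] - vol$ct[bg]), -220)
  ext <- lab == match("exterior", catphanqa:::LABEL_LEVELS)
  expect_identical(d4$ct[ext], vol$ct[ext])
  # per-class map must cover all classes present
  expect_error(apply_drift(vol, 200, list(teflon = c(0, -50)), 100),
               class = "configuration_error")
  # monotone in mAs, matching direct evaluation of the drift formula
  mas <- c(100, 200, 400, 800)
  means <- vapply(mas, function(m)
    mean(apply_drift(vol, m, dmap, 100)$ct[bg]), 0)
  oracle <- mean(vol$ct[bg]) - 110 * log2(mas / 100)
  expect_equal(means, oracle)
  expect_true(all(diff(means) < 0))
})

test_that("blur has the stated PSF width and is the identity at zero FWHM", {
  # step edge: 25-75% width of a Gaussian-blurred edge is ~ FWHM / 1.75
  n <- 80
  step <- flat_volume(0, n = n)
  step$ct[, 41:n, 1] <- 1000
  expect_identical(apply_blur(step, 0)$ct, step$ct)
  fwhm <- 4
  b <- apply_blur(step, fwhm)
  prof <- b$ct[n / 2, , 1]
  # strictly monotone part of the edge, away from the array boundary
  sub <- intersect(which(prof > 1 & prof < 999), 20:60)
  x25 <- approx(prof[sub], sub, xout = 250)$y
  x75 <- approx(prof[sub], sub, xout = 750)$y
  expect_equal(x75 - x25, fwhm / 1.75, tolerance = 0.1)
})

test_that("blur strictly reduces line-pair modulation", {
  ph <- catphan_phantom("CTP528")
  vol <- render_ideal_volume(ph, c(0.47, 0.47, 2.5), slices_per_module = 1,
                             supersample = 2)
  r0 <- measure_resolution(vol)
  r2 <- measure_resolution(apply_blur(vol, 2))
  m0 <- r0$per_group$modulation
  m2 <- r2$per_group$modulation
  ok <- !is.na(m0) & !is.na(m2) & m0 > 0.05
  expect_true(all(m2[ok] < m0[ok]))
  expect_lt(r2$max_resolvable, r0$max_resolvable)
})

test_that("noise has sigma = k / sqrt(mAs), reproducibly, without touching the global RNG", {
  vol <- flat_volume(0, n = 320)   # > 1e5 voxels
  expect_identical(apply_noise(vol, 900, 0)$ct, vol$ct)
  n1 <- apply_noise(vol, 900, 600, seed = 5)   # sigma 20
  expect_equal(sd(n1$ct), 20, tolerance = 0.01)
  n4 <- apply_noise(vol, 3600, 600, seed = 5)  # 4x mAs halves sigma
  expect_equal(sd(n4$ct) / sd(n1$ct), 0.5, tolerance = 0.01)
  expect_identical(apply_noise(vol, 900, 600, seed = 5)$ct, n1$ct)
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(apply_noise(vol, 900, 600, seed = 5))
  expect_identical(rnorm(3), before)
  expect_error(apply_noise(vol, 0, 100), class = "invalid_argument")
})

test_that("simulated scans are deterministic and carry the right rescale dialect", {
  ph <- catphan_phantom("CTP486")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- function(out) simulation_config("xvi-head-neck", 1, ph,
                                         slices_per_module = 2,
                                         out_dir = out, seed = 7)
  s1 <- simulate_scan(cfg(d1))
  s2 <- simulate_scan(cfg(d2))
  f1 <- sort(list.files(d1, pattern = "dcm$", full.names = TRUE))
  f2 <- sort(list.files(d2, pattern = "dcm$", full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_series(d1)
  expect_equal(back$rescale_intercept, -510)   # XVI dialect
  expect_identical(back$stored, s1$stored)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$total_mas, 36.1)
  expect_equal(man$truth$noise_sigma,
               man$truth$noise_coefficient / sqrt(36.1))
  obi <- simulate_scan(simulation_config("obi-full-fan", 1,
                                         catphan_phantom("CTP486"),
                                         slices_per_module = 1, seed = 1))
  expect_equal(obi$rescale_intercept, -1000)   # OBI dialect
  expect_equal(obi$voxel_size[1], 0.47)
})

test_that("with all artifacts disabled the scan decodes to the quantized ideal render", {
  ph <- catphan_phantom("CTP404")
  cfg <- simulation_config("xvi-head-neck", 1, ph,
                           artifacts = artifact_params(), slices_per_module = 1)
  img <- simulate_scan(cfg)
  ideal <- render_ideal_volume(ph, c(1, 1, 1), slices_per_module = 1)
  # integer encoding clamps below the intercept (XVI floor is -510 HU)
  expected <- pmax(round(ideal$ct - img$rescale_intercept), 0) +
    img$rescale_intercept
  expect_equal(to_ct_numbers(img), expected, ignore_attr = TRUE)
  expect_true(max(abs(to_ct_numbers(img) -
                        pmax(ideal$ct, img$rescale_intercept))) <= 0.5)
})

test_that("default artifact presets encode the emulated scanner behaviours", {
  a_xvi <- default_artifacts("xvi-chest", "large")
  expect_equal(a_xvi$noise_coefficient, 25 * sqrt(325))
  expect_equal(a_xvi$uniformity_amplitude, -288.67 / 0.49, tolerance = 1e-6)
  expect_equal(a_xvi$drift[["*"]][2], -160)
  a_obi <- default_artifacts("obi-full-fan")
  expect_equal(a_obi$noise_coefficient, 25 * sqrt(63))
  expect_length(a_obi$drift, 0)
  expect_error(artifact_params(noise_coefficient = -1),
               class = "configuration_error")
})
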