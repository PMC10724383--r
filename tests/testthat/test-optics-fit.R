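# Scattering and birefringence fitting, attenuation normalization,
# projections.

test_that("noise-free scattering fit is exact and degenerate cases are flagged", {
  cfg <- test_cfg()
  v <- simulate_psoct_slab(5, 0, 0, cfg, n_alines = 2, nz = 100,
                           surface_um = 30, seed = 1,
                           speckle = FALSE, noise = FALSE)
  sf <- fit_scattering(mean_profile(v, cfg), cfg)
  expect_equal(sf$mu_s, 5, tolerance = 1e-3)
  expect_gt(sf$r_squared, 0.999999)
  # mu_s = 0 profile after confocal correction
  v0 <- simulate_psoct_slab(0, 0, 0, cfg, n_alines = 2, nz = 100,
                            surface_um = 30, seed = 1,
                            speckle = FALSE, noise = FALSE)
  expect_equal(fit_scattering(mean_profile(v0, cfg), cfg)$mu_s, 0,
               tolerance = 1e-6)
  # flat profile -> zero with a low-confidence flag
  flat <- depth_profile(seq(0, 297, by = 3), rep(1, 100), surface_um = 30)
  ff <- fit_scattering(flat, cfg)
  expect_equal(ff$mu_s, 0)
  # too few samples rejected
  expect_error(fit_scattering(depth_profile(c(80, 90), c(1, 1)), cfg),
               "at least 10")
})

test_that("speckled slabs recover mu_s in {2, 5, 8} within 5%", {
  cfg <- test_cfg()
  for (mu in c(2, 5, 8)) {
    v <- simulate_psoct_slab(mu, 0, 0, cfg, n_alines = 1600, nz = 100,
                             surface_um = 30, seed = 100 + mu)
    sf <- fit_scattering(mean_profile(v, cfg), cfg)
    expect_lt(abs(sf$mu_s - mu) / mu, 0.05)
  }
})

test_that("fitted slope responds monotonically to increasing mu_s", {
  cfg <- test_cfg()
  mus <- c(2, 5, 8, 12)
  est <- vapply(mus, function(mu) {
    v <- simulate_psoct_slab(mu, 0, 0, cfg, n_alines = 800, nz = 100,
                             surface_um = 30, seed = 40 + mu)
    fit_scattering(mean_profile(v, cfg), cfg)$mu_s
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("birefringence fit inverts the double-pass slope convention", {
  cfg <- test_cfg()
  v <- simulate_psoct_slab(5, 5e-4, 20, cfg, n_alines = 4, nz = 100,
                           surface_um = 30, seed = 1,
                           speckle = FALSE, noise = FALSE)
  prof <- psoct2pm:::volume_depth_profile(v, cfg)
  bf <- fit_birefringence(prof, cfg)
  slope_expect <- 2 * 5e-4 * 360 / cfg$center_wavelength_um * 1000  # deg/mm
  expect_equal(bf$slope_deg_mm, slope_expect, tolerance = 0.02 * slope_expect)
  expect_equal(bf$delta_n, 5e-4, tolerance = 0.02 * 5e-4)
  # delta_n = 0 -> slope 0
  v0 <- simulate_psoct_slab(5, 0, 0, cfg, n_alines = 4, nz = 100,
                            surface_um = 30, seed = 1,
                            speckle = FALSE, noise = FALSE)
  bf0 <- fit_birefringence(psoct2pm:::volume_depth_profile(v0, cfg), cfg)
  expect_equal(bf0$slope_deg_mm, 0, tolerance = 1e-6)
})

test_that("samples past the 90-degree wrap are excluded without harming the fit", {
  cfg <- test_cfg()
  # strong birefringence wraps within the imaged depth
  v <- simulate_psoct_slab(3, 1.5e-3, 10, cfg, n_alines = 4, nz = 120,
                           surface_um = 0, seed = 1,
                           speckle = FALSE, noise = FALSE)
  prof <- psoct2pm:::volume_depth_profile(v, cfg)
  expect_gt(max(prof$retardance_deg, na.rm = TRUE), 85)   # wrap reached
  bf <- fit_birefringence(prof, cfg, fit_band_um = c(10, 250))
  expect_equal(bf$delta_n, 1.5e-3, tolerance = 0.02 * 1.5e-3)
})

test_that("joint two-region recovery stays within 5% for mu_s and delta_n", {
  cfg <- optical_config(psoct_fov_um = 360)
  ph <- tissue_phantom(width_um = 360, height_um = 150, pattern = "two_region")
  tiles <- simulate_psoct_tiles(ph, NULL, cfg, seed = 9, tile_px = 120,
                                depth_um = 300)
  t1 <- tiles$tiles[[1]]
  # region boundary sits at tile column 60; stay clear of it
  halves <- list(gray = 1:55, white = 66:120)
  truth <- list(gray = c(4, 5e-5), white = c(10, 4e-4))
  for (side in names(halves)) {
    sub <- pol_volume(t1$co[halves[[side]], , , drop = FALSE],
                      t1$cross[halves[[side]], , , drop = FALSE],
                      list(surface_um = 30))
    prof <- psoct2pm:::volume_depth_profile(sub, cfg)
    sf <- fit_scattering(prof, cfg)
    expect_lt(abs(sf$mu_s - truth[[side]][1]) / truth[[side]][1], 0.05)
    if (side == "white") {
      bf <- fit_birefringence(prof, cfg)
      expect_lt(abs(bf$delta_n - truth[[side]][2]) / truth[[side]][2], 0.05)
    }
  }
})

test_that("higher-scattering tissue renders darker at depth", {
  cfg <- test_cfg()
  deep <- function(mu) {
    v <- simulate_psoct_slab(mu, 0, 0, cfg, n_alines = 400, nz = 100,
                             surface_um = 30, seed = mu)
    mean(compute_reflectivity(v)[, , 60:80])
  }
  expect_lt(deep(10), deep(4))
})

test_that("depth-attenuation normalization equalizes frames, keeps contrast", {
  set.seed(5)
  nx <- 80; ny <- 80; nz <- 10
  base <- 100 + gauss_blur(matrix(rnorm(nx * ny, sd = 5), nx, ny), 3)
  tube <- draw_disks(nx, ny, rep(40, ny), 1:ny, rep(6, ny), 1)
  frame <- base * (1 - 0.5 * tube)
  vol <- array(0, c(nx, ny, nz))
  for (iz in 1:nz) vol[, , iz] <- frame * exp(-2 * 8 * (iz - 1) * 3 / 1000)
  out <- depth_attenuation_normalize(vol)
  mus <- apply(out$volume, 3, mean)
  expect_lt(diff(range(mus)) / mean(mus), 1e-6)
  # dark-tube contrast ratio retained (>= 90%)
  contrast <- function(f) 1 - mean(f[tube > 0]) / mean(f[tube == 0])
  expect_gt(contrast(out$volume[, , nz]), 0.9 * contrast(frame))
  # constant volume passes through unchanged up to the DC convention
  cv <- array(3, c(20, 20, 4))
  expect_equal(depth_attenuation_normalize(cv)$volume, cv, tolerance = 1e-9)
})

test_that("projections obey their order relations and edge cases", {
  set.seed(6)
  v <- array(runif(20 * 20 * 6), c(20, 20, 6))
  expect_equal(project(v, "MIP", c(3, 3)), v[, , 3])
  mip <- project(v, "MIP"); aip <- project(v, "AIP"); mnp <- project(v, "minIP")
  expect_true(all(mip >= aip & aip >= mnp))
  expect_error(project(v, "AIP", c(4, 2)), "empty")
  # an oblique dark vessel crosses the depth frames: each single frame
  # holds one segment, the minIP accumulates the full track
  nxv <- 60
  vv <- array(100 + rnorm(nxv * nxv * 6, sd = 2), c(nxv, nxv, 6))
  track <- matrix(0, nxv, nxv)
  for (iz in 1:6) {
    seg <- draw_disks(nxv, nxv, rep(5 + iz * 8, nxv), 1:nxv, rep(3, nxv), 1)
    vv[, , iz] <- vv[, , iz] * (1 - 0.5 * seg)
    track <- pmax(track, seg)
  }
  contrast <- function(f) 1 - mean(f[track > 0]) / mean(f[track == 0])
  expect_gt(contrast(project(vv, "minIP")), contrast(vv[, , 1]) + 0.1)
})

test_that("tidiers expose the fit results as tibbles", {
  cfg <- test_cfg()
  v <- simulate_psoct_slab(5, 4e-4, 0, cfg, n_alines = 4, nz = 100,
                           surface_um = 30, seed = 1,
                           speckle = FALSE, noise = FALSE)
  prof <- psoct2pm:::volume_depth_profile(v, cfg)
  sf <- fit_scattering(prof, cfg)
  expect_equal(tidy(sf)$estimate[[1]], sf$mu_s)
  expect_s3_class(glance(sf), "tbl_df")
  bf <- fit_birefringence(prof, cfg)
  expect_equal(tidy(bf)$estimate[[2]], bf$delta_n)
})
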