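# Cell detection and pairing, count correspondence, vessel segmentation
# and cross-modality overlay.

test_that("dark-spot detector finds planted somata accurately and scale-invariantly", {
  fl <- fluorophore_phantom(600, 600, granule_density_mm2 = 0,
                            granules_per_cell = 0,
                            cell_density_mm2 = 140, n_vessels = 0, seed = 7)
  tp <- simulate_2pm_tiles(fl, optical_config(psoct_fov_um = 600),
                           seed = 7, noise_sd = 0.01, confound = NULL)
  img <- tp$tiles[[1]]$short
  sp <- detect_dark_spots(img)
  cm <- fl$cells
  d <- sqrt(outer(sp$x_um, cm$x_um, "-")^2 + outer(sp$y_um, cm$y_um, "-")^2)
  nearest <- apply(d, 2, min)
  expect_gte(mean(nearest <= 2), 0.95)           # recall, localization <= 2 um
  expect_lt(nrow(sp), 1.2 * nrow(cm))            # few spurious detections
  # equivariance under global intensity scaling
  sp5 <- detect_dark_spots(img * 5)
  expect_equal(sp5$x_px, sp$x_px)
  expect_equal(sp5$score, sp$score, tolerance = 1e-9)
  # nothing planted, nothing found
  fl0 <- fluorophore_phantom(300, 300, granule_density_mm2 = 0,
                             granules_per_cell = 0, cell_density_mm2 = 0,
                             n_vessels = 0, seed = 1)
  tp0 <- simulate_2pm_tiles(fl0, optical_config(psoct_fov_um = 400),
                            seed = 1, noise_sd = 0.01, confound = NULL)
  expect_equal(nrow(detect_dark_spots(tp0$tiles[[1]]$short)), 0)
})

test_that("cell pairing follows the pairing radius and scores well on the phantom", {
  spots <- tibble::tibble(x_px = c(50, 150), y_px = c(50, 150),
                          x_um = c(100, 300), y_um = c(100, 300),
                          r_um = 8, score = 1)
  near <- tibble::tibble(id = 1L, px_count = 10L, cx = 55.5, cy = 50.5,
                         r_eq_um = 3)  # 10 um from spot 1 in x
  cells <- pair_cells(spots, near, r_pair_um = 15, pixel_um = 2)
  expect_equal(nrow(cells), 1)
  far <- tibble::tibble(id = 1L, px_count = 10L, cx = 60.5, cy = 50.5,
                        r_eq_um = 3)  # 20 um away
  expect_equal(nrow(pair_cells(spots, far, r_pair_um = 15, pixel_um = 2)), 0)

  # full pipeline on a vessel-free phantom: F1 >= 0.9 and count within 10%
  fl <- fluorophore_phantom(600, 600, cell_density_mm2 = 120,
                            granule_density_mm2 = 150, n_vessels = 0,
                            seed = 17)
  tp <- simulate_2pm_tiles(fl, optical_config(psoct_fov_um = 600),
                           seed = 17, noise_sd = 0.02, confound = NULL)
  t1 <- tp$tiles[[1]]
  spots <- detect_dark_spots(t1$short)
  gs <- segment_granules(t1$long)
  cells <- pair_cells(spots, gs)
  truth <- tibble::tibble(x_um = fl$cells$x_um, y_um = fl$cells$y_um)
  rep <- count_correspondence(cells, truth, tol_um = 10)
  precision <- rep$matched / nrow(cells)
  recall <- rep$matched / nrow(truth)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.9)
  expect_lt(abs(nrow(cells) - nrow(truth)) / nrow(truth), 0.10)
})

test_that("correspondence rate matches its closed-form expectation", {
  set.seed(23)
  a <- tibble::tibble(x_um = runif(400, 0, 2000), y_um = runif(400, 0, 2000))
  expect_equal(count_correspondence(a, a)$rate_pct, 100)
  b_far <- dplyr::mutate(a, x_um = x_um + 5000)
  expect_equal(count_correspondence(a, b_far)$rate_pct, 0)
  # 10% random deletions: rate -> 2 * 0.9 / 1.9 * 100 ~ 94.7%
  rates <- vapply(1:20, function(i) {
    keep <- runif(400) > 0.1
    count_correspondence(a, a[keep, ], tol_um = 10)$rate_pct
  }, numeric(1))
  expect_equal(mean(rates), 200 * 0.9 / 1.9, tolerance = 0.5)
  # symmetric in its arguments
  keep <- runif(400) > 0.1
  expect_equal(count_correspondence(a, a[keep, ])$rate_pct,
               count_correspondence(a[keep, ], a)$rate_pct)
  # empty-set conventions
  e <- tibble::tibble(x_um = numeric(), y_um = numeric())
  expect_equal(count_correspondence(e, e)$rate_pct, 100)
  expect_equal(count_correspondence(a, e)$rate_pct, 0)
})

test_that("vessel segmentation covers a planted tube and stays silent on noise", {
  set.seed(24)
  nx <- 150; ny <- 150; nz <- 6
  vol <- array(100, c(nx, ny, nz)) + array(rnorm(nx * ny * nz, sd = 2),
                                           c(nx, ny, nz))
  tube <- draw_disks(nx, ny, rep(75, ny), 1:ny, rep(40 / 3, ny), 1)
  for (iz in 1:nz) vol[, , iz] <- vol[, , iz] * (1 - 0.5 * tube)
  vm <- segment_vessels_psoct(vol, pixel_um = 3, radii_um = c(10, 80))
  centerline <- cbind(75, 1:ny)
  coverage <- mean(vapply(1:nz, function(iz) mean(vm$mask[, , iz][centerline]),
                          numeric(1)))
  expect_gte(coverage, 0.9)
  # empty phantom -> empty mask
  noise_only <- array(100, c(80, 80, 3)) + array(rnorm(80 * 80 * 3), c(80, 80, 3))
  expect_equal(sum(segment_vessels_psoct(noise_only, pixel_um = 3)$mask), 0)
  # dilation contains the original mask
  m2d <- vm$mask[, , 1]
  expect_true(all(m2d <= dilate_mask(m2d, 1)))
})

test_that("overlay profiles co-localize a registered vessel and report planted offsets", {
  set.seed(25)
  nx <- 200
  mk <- function(shift_px_2pm = 0) {
    img <- matrix(100 + rnorm(nx * nx, sd = 1), nx, nx)
    tube <- draw_disks(nx, nx, rep(100 + shift_px_2pm, nx), 1:nx, rep(8, nx), 1)
    img * (1 - 0.5 * tube)
  }
  tpm <- mk(0)
  # PSOCT image on a 1.5x coarser grid of the same scene
  psoct <- resize_bilinear(mk(0), round(nx / 1.5), round(nx / 1.5))
  tr <- modality_transform(1.5, c(0, 0))
  seg <- list(p0 = c(60, 100), p1 = c(140, 100))
  ov <- overlay_and_profile(psoct, tpm, tr, seg, extremum = "min")
  expect_lt(abs(ov$offset_um), 2)
  # planted 6 um (3 px) mis-registration reads back as ~6 um
  tpm_shift <- mk(3)
  ov2 <- overlay_and_profile(psoct, tpm_shift, tr, seg, extremum = "min")
  expect_equal(abs(ov2$offset_um), 6, tolerance = 2)
  # empty-mask overlay reduces to the 2PM image in the green channel
  ov3 <- overlay_and_profile(matrix(0, 100, 100), tpm, tr, seg)
  expect_equal(ov3$composite[, , 1], matrix(0, nx, nx))
  expect_error(overlay_and_profile(psoct, tpm, tr,
                                   list(p0 = c(-5, 10), p1 = c(50, 10))),
               "outside")
})
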