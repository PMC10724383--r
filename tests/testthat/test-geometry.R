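# Geometry chain: curvature, unwarp, shading, stitching, registration,
# assembly.

test_that("field curvature is recovered and flattening is guarded", {
  cfg <- test_cfg()
  gt <- simulate_grid_target(system_confound(field_curvature_um = 12),
                             cfg, pitch_um = 54, size_px = 120)
  lut <- estimate_field_curvature(gt$surface_volume, cfg$axial_pixel_um)
  rms_px <- sqrt(mean((lut$offset_um - gt$true_curvature_um)^2)) /
    cfg$axial_pixel_um
  expect_lt(rms_px, 0.5)
  # flat surface -> zero LUT
  g0 <- simulate_grid_target(system_confound(field_curvature_um = 0),
                             cfg, pitch_um = 54, size_px = 80)
  l0 <- estimate_field_curvature(g0$surface_volume, cfg$axial_pixel_um)
  expect_lt(max(abs(l0$offset_px)), 0.1)
  # applying the LUT flattens; applying twice is refused
  flat <- flatten_volume(gt$surface_volume, lut)
  iz <- apply(flat, c(1, 2), which.max)
  expect_lte(diff(range(iz)), 2)
  expect_error(flatten_volume(flat, lut), "already flattened")
})

test_that("grid unwarp round-trips within 0.25 px RMS and preserves mass", {
  cfg <- test_cfg()
  gt <- simulate_grid_target(system_confound(grid_distortion = c(0.03, 0)),
                             cfg, pitch_um = 54, size_px = 150)
  w <- estimate_grid_unwarp(gt$image, gt$pitch_px)
  und <- warp_points(w, as.matrix(gt$distorted_centroids), "inverse")
  rms <- sqrt(mean((und - as.matrix(gt$ideal_centroids))^2))
  expect_lt(rms, 0.25)
  # identity warp for an undistorted target
  g0 <- simulate_grid_target(system_confound(grid_distortion = c(0, 0)),
                             cfg, pitch_um = 54, size_px = 150)
  w0 <- estimate_grid_unwarp(g0$image, g0$pitch_px)
  p <- as.matrix(expand.grid(x = seq(20, 130, 10), y = seq(20, 130, 10)))
  expect_lt(max(abs(warp_points(w0, p, "forward") - p)), 0.05)
  # resampling preserves the image mean within 1%
  ui <- apply_unwarp(gt$image, w)
  expect_lt(abs(mean(ui) / mean(gt$image) - 1), 0.01)
  expect_error(estimate_grid_unwarp(gt$image * 0 + 1e-9, gt$pitch_px))
})

test_that("shading gain is recovered within 2% and correction is equivariant", {
  set.seed(11)
  cf <- system_confound(shading_amplitude = 0.25)
  gain_true <- psoct2pm:::shading_gain(cf, 80, 80)
  tiles <- lapply(1:24, function(i)
    gain_true * matrix(100 + rnorm(6400, sd = 1), 80, 80))
  cs <- correct_shading(tiles)
  expect_lt(max(abs(cs$gain / gain_true - 1)), 0.02)
  # unity shading -> gain ~ 1
  flat_tiles <- lapply(1:24, function(i) matrix(100 + rnorm(6400, sd = 1), 80, 80))
  cs0 <- correct_shading(flat_tiles)
  expect_lt(max(abs(cs0$gain - 1)), 0.01)
  # scale equivariance
  cs2 <- correct_shading(lapply(tiles, function(t) 2 * t))
  expect_equal(cs2$tiles[[1]], 2 * cs$tiles[[1]], tolerance = 1e-9)
  # too few tiles -> unity fallback with a warning
  expect_warning(few <- correct_shading(tiles[1:3]), "fewer than")
  expect_true(few$fallback)
})

test_that("stitching recovers planted offsets within 1 px per edge", {
  set.seed(12)
  big <- gauss_blur(matrix(runif(300 * 300), 300, 300), 2)
  offs <- expand.grid(x = c(0, 130), y = c(0, 130))
  tiles <- lapply(1:4, function(k)
    big[offs$x[k] + 1:160, offs$y[k] + 1:160] +
      matrix(rnorm(160^2, sd = 0.02), 160, 160))   # SNR >> 10
  lay <- tibble::tibble(tile = 1:4, tile_i = rep(1:2, 2), tile_j = rep(1:2, each = 2),
                        nominal_x = offs$x + c(3, -2, 4, 0),
                        nominal_y = offs$y + c(-3, 2, 0, 4))
  st <- stitch_tiles(tiles, lay)
  rel <- cbind(st$layout$x - st$layout$x[1], st$layout$y - st$layout$y[1])
  tru <- cbind(offs$x - offs$x[1], offs$y - offs$y[1])
  expect_lte(max(abs(rel - tru)), 1)
  expect_true(all(abs(st$edges$residual_dx[st$edges$used]) <= 1))
  # single tile -> mosaic is the tile
  st1 <- stitch_tiles(tiles[1], lay[1, ])
  expect_equal(st1$mosaic, tiles[[1]], tolerance = 1e-12)
  # permutation invariance up to the anchor
  perm <- c(3, 1, 4, 2)
  st2 <- stitch_tiles(tiles[perm], dplyr::mutate(lay[perm, ], tile = 1:4))
  rel2 <- cbind(st2$layout$x - st2$layout$x[perm == 1],
                st2$layout$y - st2$layout$y[perm == 1])[order(perm), ]
  expect_equal(unname(rel2), unname(rel))
})

test_that("modality registration: analytic scale, exact planted shift, inverse consistency", {
  cfg <- optical_config()
  expect_equal(modality_scale(cfg), 1.5)
  set.seed(13)
  scene <- gauss_blur(matrix(runif(800 * 800), 800, 800), 4)
  dx <- -50; dy <- 113
  tpm <- scene[300 + 1:300, 300 + 1:300]
  u <- 1:280; v <- 1:280
  xs <- ((u - 0.5) * 1.5 + 0.5) + dx + 300
  ys <- ((v - 0.5) * 1.5 + 0.5) + dy + 300
  g <- expand.grid(x = xs, y = ys)
  psoct <- matrix(bilinear_sample(scene, g$x, g$y), 280, 280)
  tr <- register_modalities(psoct, tpm, cfg, max_shift_px = 150)
  expect_identical(tr$shift, c(dx, dy))
  # identical images register at zero shift
  tr0 <- register_modalities(tpm[1:200, 1:200], resize_bilinear(
    tpm[1:200, 1:200], 300, 300), optical_config(), max_shift_px = 30)
  expect_identical(tr0$shift, c(0L, 0L) * 1)
  # A->B composed with B->A is the identity within a pixel
  back <- modality_transform(1 / tr$scale, -round(tr$shift / tr$scale))
  comp <- compose_transforms(tr, back)
  expect_equal(comp$scale, 1)
  expect_lte(max(abs(comp$shift)), 1)
})

test_that("slice assembly keeps structure continuous across cuts", {
  cfg <- test_cfg()
  nx <- 40; ny <- 40
  axial <- cfg$axial_pixel_um
  nz_slice <- 90   # 270 um imaged per slice
  # oblique tube through a 450-um stack, cut into 3 slices of 150 um
  make_slice <- function(s) {
    vol <- array(100, c(nx, ny, nz_slice))
    for (iz in seq_len(nz_slice)) {
      zg <- (s - 1) * 150 + (iz - 1) * axial   # global depth of this plane
      tube <- draw_disks(nx, ny, 8 + zg * 0.05, 20, 4, 1)
      vol[, , iz] <- vol[, , iz] * (1 - 0.6 * tube)
    }
    vol
  }
  slices <- lapply(1:3, make_slice)
  out <- assemble_volume(slices, axial_pixel_um = axial,
                         slice_thickness_um = 150, band_um = c(50, 200),
                         surface_um = 0)
  expect_equal(dim(out$volume)[3], 3 * round(150 / axial))
  centers <- vapply(seq_len(dim(out$volume)[3]), function(iz) {
    dip <- pmax(100 - apply(out$volume[, , iz], 1, mean), 0)
    sum(seq_len(nx) * dip) / sum(dip)   # intensity-weighted centerline
  }, numeric(1))
  expect_true(all(abs(diff(centers)) <= 1))
  nzb <- round(150 / axial)
  for (b in c(nzb, 2 * nzb)) {          # the cut boundaries specifically
    expect_lte(abs(centers[b + 1] - centers[b]), 1)
  }
  # single slice, and exact down-sampling arithmetic
  one <- assemble_volume(slices[1], axial, 150, c(50, 200))
  expect_equal(dim(one$volume)[3], round(150 / axial))
  dsv <- downsample_volume(array(1, c(40, 40, 50)), c(10, 10, 10))
  expect_equal(dim(dsv), c(4, 4, 5))
  expect_equal(prod(dim(dsv)), 40 * 40 * 50 / 1000)   # exactly 1000x fewer
})

test_that("full geometric chain reproduces planted positions within 1 px and 1 voxel", {
  cfg <- optical_config(psoct_fov_um = 360)
  cf <- system_confound(grid_distortion = c(0.03, 0), field_curvature_um = 9,
                        shading_amplitude = 0.2)
  # calibration from the grid target
  gt <- simulate_grid_target(cf, cfg, pitch_um = 45, dot_sigma_um = 5,
                             size_px = 120)
  lut <- estimate_field_curvature(gt$surface_volume, cfg$axial_pixel_um)
  warp <- estimate_grid_unwarp(gt$image, gt$pitch_px)
  # lateral truth: distorted dots unwarp to the ideal lattice
  und <- warp_points(warp, as.matrix(gt$distorted_centroids), "inverse")
  expect_lt(max(sqrt(rowSums((und - as.matrix(gt$ideal_centroids))^2))), 1)
  # axial truth: flattened surface sits within one voxel everywhere
  flat <- flatten_volume(gt$surface_volume, lut)
  iz <- apply(flat, c(1, 2), which.max)
  expect_lte(max(abs(iz - stats::median(iz))), 1)
  # tiling truth: the speckle-free 2PM channel is stitched and its
  # globally optimized coordinates, scaled by the pixel-size ratio, are
  # transferred to the synchronously acquired PSOCT grid
  cfg2 <- optical_config(psoct_fov_um = 270)
  fl <- fluorophore_phantom(360, 360, seed = 2, n_vessels = 2)
  tp <- simulate_2pm_tiles(fl, cfg2, seed = 2, noise_sd = 0.02,
                           confound = NULL)   # 135 px tiles on the 2 um grid
  lay <- tp$layout
  set.seed(8)
  lay$nominal_x <- lay$true_x + sample(-3:3, nrow(lay), replace = TRUE)
  lay$nominal_y <- lay$true_y + sample(-3:3, nrow(lay), replace = TRUE)
  st <- stitch_tiles(lapply(tp$tiles, `[[`, "long"), lay)
  rel <- cbind(st$layout$x - st$layout$x[1], st$layout$y - st$layout$y[1])
  tru <- cbind(lay$true_x - lay$true_x[1], lay$true_y - lay$true_y[1])
  expect_lte(max(abs(rel - tru)), 1)
  # transferred PSOCT coordinates (3 um grid) inherit sub-pixel accuracy
  scale <- modality_scale(cfg2)
  psoct_rel <- rel / scale
  psoct_tru <- tru / scale
  expect_lte(max(abs(psoct_rel - psoct_tru)), 1)
})
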