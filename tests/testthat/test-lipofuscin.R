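# Lipofuscin segmentation and windowed morphometry.

test_that("segmentation anchors: uniform image, single disk, threshold monotonicity", {
  expect_equal(nrow(segment_granules(matrix(5, 120, 120))$granules), 0)
  # one bright disk radius 5 px, contrast 3x
  img <- draw_disks(150, 150, 75, 75, 5, 2, img = matrix(1, 150, 150),
                    accumulate = TRUE)
  gs <- segment_granules(img)
  expect_equal(nrow(gs$granules), 1)
  expect_lt(abs(gs$granules$px_count - pi * 25) / (pi * 25), 0.10)
  # raising the bound never grows the segmented area
  areas <- vapply(c(1.1, 1.22, 1.5, 2), function(b)
    sum(segment_granules(img, lower_bound = b)$labels > 0), numeric(1))
  expect_true(all(diff(areas) <= 0))
  # Huang diagnostic is recorded
  expect_true(is.finite(gs$params$huang_threshold))
})

test_that("noise-free phantom granules are recovered with precision and recall >= 0.99", {
  fl <- fluorophore_phantom(600, 600, granule_density_mm2 = 550,
                            cell_density_mm2 = 0, granules_per_cell = 0,
                            n_vessels = 0, seed = 11)
  expect_gt(nrow(fl$granules), 150)
  tp <- simulate_2pm_tiles(fl, optical_config(psoct_fov_um = 600),
                           seed = 5, noise_sd = 0, confound = NULL)
  t1 <- tp$tiles[[1]]
  gs <- segment_granules(t1$long)
  tm <- t1$truth$granule_labels
  truth_ids <- unique(tm[tm > 0])
  sm <- gs$labels > 0
  recall <- mean(vapply(truth_ids, function(id) mean(sm[tm == id]) > 0.5,
                        logical(1)))
  precision <- mean(vapply(seq_len(nrow(gs$granules)), function(i)
    any(tm[gs$labels == i] > 0), logical(1)))
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})

test_that("window metrics match the hand-computed formulas", {
  # an entirely lipofuscin-filled window
  full <- structure(list(labels = matrix(1L, 100, 100),
                         granules = tibble::tibble(id = 1L, px_count = 10000L,
                                                   cx = 50, cy = 50,
                                                   r_eq_um = 2 * sqrt(10000 / pi)),
                         params = list()), class = "granule_set")
  wm <- window_metrics(full)
  expect_equal(wm$area_fraction_pct, 100)
  expect_equal(wm$mean_radius_um, 2 * sqrt(10000 / pi), tolerance = 1e-12)
  # one 5-px-radius disk: P1 ~ 78.5, N = 1 -> mean radius ~ 10 um
  lab <- matrix(0L, 100, 100)
  lab <- draw_disks(100, 100, 50, 50, 5, 1L, img = lab)
  one <- structure(list(labels = lab, granules = tibble::tibble(id = 1L),
                        params = list()), class = "granule_set")
  w1 <- window_metrics(one)
  expect_equal(w1$mean_radius_um, 10, tolerance = 0.25)
  # four granules in one window -> density 4 / 0.04 = 100 per mm^2
  lab4 <- matrix(0L, 100, 100)
  for (k in 1:4) lab4 <- draw_disks(100, 100, 20 * k, 20 * k, 3, k, img = lab4)
  four <- structure(list(labels = lab4, granules = tibble::tibble(id = 1:4),
                         params = list()), class = "granule_set")
  expect_equal(window_metrics(four)$number_density_mm2, 100)
  # N = 0 window: radius undefined, density 0
  none <- structure(list(labels = matrix(0L, 100, 100),
                         granules = tibble::tibble(id = integer()),
                         params = list()), class = "granule_set")
  w0 <- window_metrics(none)
  expect_true(is.na(w0$mean_radius_um))
  expect_equal(w0$number_density_mm2, 0)
})

test_that("pixel mass is conserved over non-overlapping windows", {
  fl <- fluorophore_phantom(400, 400, granule_density_mm2 = 400,
                            cell_density_mm2 = 0, granules_per_cell = 0,
                            n_vessels = 0, seed = 21)
  tp <- simulate_2pm_tiles(fl, optical_config(psoct_fov_um = 400),
                           seed = 6, noise_sd = 0, confound = NULL)
  gs <- segment_granules(tp$tiles[[1]]$long)
  wm <- window_metrics(gs, window_px = 100, step_px = 100)
  expect_equal(sum(wm$p1),
               sum(gs$labels[1:200, 1:200] > 0))
})

test_that("doubling the planted density doubles the measured number density", {
  dens <- function(d, seed) {
    fl <- fluorophore_phantom(600, 600, granule_density_mm2 = d,
                              cell_density_mm2 = 0, granules_per_cell = 0,
                              n_vessels = 0, seed = seed)
    tp <- simulate_2pm_tiles(fl, optical_config(psoct_fov_um = 600),
                             seed = seed, noise_sd = 0, confound = NULL)
    gs <- segment_granules(tp$tiles[[1]]$long)
    mean(window_metrics(gs)$number_density_mm2)
  }
  d1 <- mean(vapply(1:3, function(s) dens(250, s), numeric(1)))
  d2 <- mean(vapply(1:3, function(s) dens(500, s + 10), numeric(1)))
  # Poisson error at ~90-180 granules per draw, 3 draws: a few percent
  expect_lt(abs(d2 / d1 - 2), 0.25)
})

test_that("age regression recovers planted trends", {
  # exactly collinear points -> R^2 = 1
  d <- tibble::tibble(age = c(60, 70, 80, 90),
                      tissue_class = "gray",
                      area_fraction_pct = 1 + 0.1 * c(60, 70, 80, 90))
  tr <- suppressWarnings(regress_vs_age(d, metrics = "area_fraction_pct"))
  expect_equal(tr$r_squared, 1, tolerance = 1e-12)
  expect_equal(tr$slope, 0.1, tolerance = 1e-12)
  # zero-slope data: fitted slope statistically indistinguishable from 0
  set.seed(31)
  d0 <- tibble::tibble(age = rep(seq(60, 90, 5), 2),
                       tissue_class = "white",
                       number_density_mm2 = 300 + rnorm(14, sd = 10))
  t0 <- regress_vs_age(d0, metrics = "number_density_mm2")
  expect_gt(t0$p_value, 0.05)
  # planted density slope across an aging series, recovered within 10%
  ages <- c(60, 65, 70, 75, 80, 85)
  slope_true <- 8    # granules per mm^2 per year
  meas <- vapply(seq_along(ages), function(i) {
    # per-sample mean over two replicate blocks, as a study would use
    mean(vapply(0:1, function(rep) {
      fl <- fluorophore_phantom(800, 800,
                                granule_density_mm2 = 150 + slope_true * (ages[i] - 60),
                                cell_density_mm2 = 0, granules_per_cell = 0,
                                n_vessels = 0, seed = 40 + 2 * i + rep)
      tp <- simulate_2pm_tiles(fl, optical_config(psoct_fov_um = 800),
                               seed = 40 + 2 * i + rep, noise_sd = 0,
                               confound = NULL)
      gs <- segment_granules(tp$tiles[[1]]$long)
      mean(window_metrics(gs)$number_density_mm2)
    }, numeric(1)))
  }, numeric(1))
  tr2 <- regress_vs_age(tibble::tibble(age = ages, tissue_class = "gray",
                                       number_density_mm2 = meas),
                        metrics = "number_density_mm2")
  expect_lt(abs(tr2$slope - slope_true) / slope_true, 0.10)
  # fewer than 3 samples rejected
  expect_error(regress_vs_age(d[1:2, ], metrics = "area_fraction_pct"),
               "at least 3")
})
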