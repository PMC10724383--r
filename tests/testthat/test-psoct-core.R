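# Polarization estimators and system-birefringence compensation.

test_that("reflectivity follows 10 log10 of total power over the floor", {
  a <- pol_ascan(co = c(1, 0), cross = c(0, sqrt(100)))
  db <- compute_reflectivity(a, floor_power = 1)
  expect_equal(db[1], 0)
  expect_equal(db[2], 20)
  # all-zero voxel flagged at the floor
  z <- pol_ascan(co = c(0 + 0i), cross = c(0 + 0i))
  expect_equal(compute_reflectivity(z, floor_power = 1), 0)
})

test_that("noise-free dB slope of a slab recovers 2 mu_s", {
  cfg <- test_cfg()
  v <- simulate_psoct_slab(5, 0, 0, cfg, n_alines = 2, nz = 100,
                           surface_um = 30, seed = 1,
                           speckle = FALSE, noise = FALSE)
  db <- apply(compute_reflectivity(v), 3, mean)
  z <- (seq_len(100) - 1) * cfg$axial_pixel_um
  env <- confocal_envelope(z, 30 + cfg$confocal_focus_depth_um,
                           cfg$confocal_parameter_um)
  band <- z >= 80 & z <= 230
  slope_db_mm <- stats::coef(stats::lm(I(db[band] - 10 * log10(env[band])) ~
                                         I(z[band] / 1000)))[2]
  # -2 mu_s in natural log equals -20 mu_s / ln(10) in dB
  expect_equal(unname(slope_db_mm), -10 * 10 / log(10), tolerance = 1e-6)
})

test_that("retardance estimator hits its closed-form anchors and range", {
  expect_equal(compute_retardance(pol_ascan(1 + 0i, 0 + 0i)), 0)
  expect_equal(compute_retardance(pol_ascan(1 + 0i, 1 + 0i)), 45)
  expect_equal(compute_retardance(pol_ascan(0 + 0i, 1 + 0i)), 90)
  # flagged invalid at the noise floor
  a <- pol_ascan(co = c(1e-8 + 0i), cross = c(1e-8 + 0i))
  expect_true(is.na(compute_retardance(a, floor_power = 1e-10)))
})

test_that("orientation is equivariant, zeroed on the mirror, NA below the floor", {
  cfg <- test_cfg()
  cm <- calibrate_compensation(simulate_mirror_scan(test_confound(), cfg))
  base <- surface_orientation(apply_compensation(
    simulate_retarder_sample(45, 0, test_confound(), cfg), cm))
  expect_equal(base, 0, tolerance = 1e-6)
  rot <- surface_orientation(apply_compensation(
    simulate_retarder_sample(45, 30, test_confound(), cfg), cm))
  expect_equal(wrap_orientation(rot - base), 30, tolerance = 1e-6)
  # zero-retardance voxel -> undefined orientation
  m <- apply_compensation(simulate_retarder_sample(0, 10, test_confound(), cfg), cm)
  expect_true(all(is.na(compute_orientation(m))))
})

test_that("calibration recovers the planted system retarder within 0.5 degrees", {
  cfg <- test_cfg()
  cm <- calibrate_compensation(simulate_mirror_scan(test_confound(70, 25), cfg))
  expect_equal(cm$retardance, 70, tolerance = 0.5)
  expect_equal(cm$axis, 25, tolerance = 0.5)
  expect_true(cm$converged)

  # independent oracle: grid search over (retardance, axis) minimizing the
  # same mirror observables, coarse-to-fine down to 0.1 degrees
  v <- psoct2pm:::mirror_state(simulate_mirror_scan(test_confound(70, 25), cfg))
  phase_ref <- psoct2pm:::ideal_mirror_co_phase()
  grid_obj <- function(rets, axs) {
    g <- expand.grid(ret = rets, ax = axs)
    f <- vapply(seq_len(nrow(g)), function(i) {
      C <- Conj(t(jones_retarder(g$ret[i], g$ax[i])))
      w <- C %*% v
      Mod(w[1])^2 + (1 - cos(Arg(w[2]) - phase_ref))
    }, numeric(1))
    g[which.min(f), ]
  }
  coarse <- grid_obj(seq(0, 90, 1), seq(-89, 90, 1))
  fine <- grid_obj(seq(coarse$ret - 1, coarse$ret + 1, 0.1),
                   seq(coarse$ax - 1, coarse$ax + 1, 0.1))
  expect_equal(cm$retardance, fine$ret, tolerance = 0.2)
  expect_equal(cm$axis, fine$ax, tolerance = 0.2)

  # zero confound -> essentially the identity
  cm0 <- calibrate_compensation(simulate_mirror_scan(test_confound(0, 0), cfg))
  expect_lt(cm0$retardance, 0.5)
  expect_lt(cm0$residual_cross_fraction, 1e-10)
})

test_that("compensation is unitary, idempotent in calibration, and fixes the sweep", {
  cfg <- test_cfg()
  cf <- test_confound(70, 25)
  cm <- calibrate_compensation(simulate_mirror_scan(cf, cfg))
  # power preserved to 1e-10 relative
  s <- simulate_retarder_sample(37, 52, cf, cfg)
  sc <- apply_compensation(s, cm)
  expect_equal(sum(Mod(sc$co)^2 + Mod(sc$cross)^2),
               sum(Mod(s$co)^2 + Mod(s$cross)^2), tolerance = 1e-10)
  # identity model leaves input unchanged
  id <- compensation_model(0, 0)
  s0 <- apply_compensation(s, id)
  expect_equal(s0$co, s$co, tolerance = 1e-12)
  # re-calibrating compensated data yields ~identity
  cm2 <- calibrate_compensation(apply_compensation(
    simulate_mirror_scan(cf, cfg), cm))
  expect_lt(cm2$retardance, 0.5)
  # the compensated retarder sweep tracks ground truth across [0, 90]
  sweep <- seq(0, 90, by = 3)
  est <- vapply(sweep, function(r)
    surface_retardance(apply_compensation(
      simulate_retarder_sample(r, 30, cf, cfg), cm)), numeric(1))
  expect_lt(max(abs(est - sweep)), 1)
})

test_that("PER improves under compensation and is deterministic", {
  cfg <- test_cfg()
  cf <- test_confound(70, 25)
  sw <- simulate_qwp_sweep(cf, cfg)
  per_pre <- compute_per(sw)
  expect_true(all(is.finite(per_pre$per_db)))
  expect_true(all(per_pre$per_db < 40))
  cm <- calibrate_compensation(simulate_mirror_scan(cf, cfg))
  per_post <- compute_per(lapply(sw, apply_compensation, m = cm))
  expect_true(all(per_post$per_db > per_pre$per_db))
  # ideal system: bounded only by the clipping floor
  per_ideal <- compute_per(simulate_qwp_sweep(NULL, cfg))
  expect_true(all(per_ideal$per_db >= 90))
  expect_true(all(per_ideal$clipped))
  # determinism
  expect_identical(compute_per(sw), compute_per(simulate_qwp_sweep(cf, cfg)))
})
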