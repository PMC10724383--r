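# Optical tissue phantom and PSOCT forward simulation.
#
# The phantom gives every downstream estimator a known ground truth: lateral
# fields of scattering coefficient, birefringence and optic-axis
# orientation, a smooth surface topography, and an instrument confound
# (system birefringence, grid distortion, field curvature, shading).
#
# Retardance bookkeeping uses the double-pass convention throughout the
# package: the reported retardance at depth z accumulates over the
# round-trip path, so its expected slope is 2 * (360 / lambda) * delta_n
# degrees per unit depth, and a birefringence fit inverts the same factor.

#' Tissue phantom with known optical properties
#'
#' Lateral fields (matrices on a regular grid) of scattering coefficient
#' mu_s (mm^-1), birefringence delta-n, in-plane optic-axis orientation
#' (degrees) and surface topography (um), plus gray/white region labels.
#' The default `two_region` pattern places low-scattering, weakly
#' birefringent "gray matter" in the left half and high-scattering,
#' birefringent "white matter" in the right half, emulating the
#' white/gray contrast of cortical blocks.
#'
#' @param width_um,height_um lateral extent in micrometres.
#' @param grid_um sampling of the phantom fields (um).
#' @param pattern `"two_region"` or `"uniform"`.
#' @param mu_s scattering coefficients, mm^-1; named `c(gray=, white=)` for
#'   `two_region`, single value for `uniform`.
#' @param delta_n birefringence per region (dimensionless).
#' @param axis_deg optic-axis orientation per region, degrees in (-90, 90].
#' @param surface_amplitude_um peak-to-center amplitude of a smooth
#'   (parabolic) surface topography; 0 = flat surface.
#' @param surface_offset_um mean surface depth below the first sampled
#'   plane, um.
#' @return a `tissue_phantom` object.
#' @export
tissue_phantom <- function(width_um = 600, height_um = 600, grid_um = 3,
                           pattern = c("two_region", "uniform"),
                           mu_s = c(gray = 4, white = 10),
                           delta_n = c(gray = 5e-5, white = 4e-4),
                           axis_deg = c(gray = 0, white = 30),
                           surface_amplitude_um = 0,
                           surface_offset_um = 30) {
  pattern <- match.arg(pattern)
  nx <- round(width_um / grid_um); ny <- round(height_um / grid_um)
  stopifnot(nx > 1, ny > 1, all(mu_s >= 0))
  if (pattern == "uniform") {
    region <- matrix("gray", nx, ny)
    mu_s <- rep_len(mu_s, 1); delta_n <- rep_len(delta_n, 1)
    axis_deg <- rep_len(axis_deg, 1)
    ms <- matrix(mu_s, nx, ny); dn <- matrix(delta_n, nx, ny)
    ax <- matrix(axis_deg, nx, ny)
  } else {
    region <- matrix(ifelse(outer(seq_len(nx) <= nx / 2, rep(TRUE, ny)),
                            "gray", "white"), nx, ny)
    pick <- function(v) matrix(ifelse(region == "gray", v[["gray"]], v[["white"]]), nx, ny)
    ms <- pick(mu_s); dn <- pick(delta_n); ax <- pick(axis_deg)
  }
  cxn <- (nx + 1) / 2; cyn <- (ny + 1) / 2
  rr <- outer(((seq_len(nx) - cxn) / (nx / 2))^2,
              ((seq_len(ny) - cyn) / (ny / 2))^2, "+") / 2
  surf <- surface_offset_um + surface_amplitude_um * rr
  structure(list(width_um = width_um, height_um = height_um, grid_um = grid_um,
                 mu_s = ms, delta_n = dn, axis_deg = wrap_orientation(ax),
                 surface_um = surf, region = region,
                 gain = matrix(1, nx, ny)),
            class = "tissue_phantom")
}

#' Plant the fluorophore phantom's vessels into a tissue phantom
#'
#' Stamps the vessel tubes as a reflectivity attenuation into the tissue
#' phantom's lateral gain field, so the same vasculature is visible (as
#' dark tubes) in the PSOCT channel and (bright/dark) in the two-photon
#' channels — the shared structure cross-modality registration relies on.
#'
#' @param phantom a [tissue_phantom()].
#' @param fl a [fluorophore_phantom()] covering the same extent.
#' @param vessel_gain multiplicative intensity factor inside vessels.
#' @return the modified [tissue_phantom()].
#' @export
plant_vessels_in_tissue <- function(phantom, fl, vessel_gain = 0.4) {
  vm <- rasterize_vessels(fl$vessels, nrow(phantom$gain), ncol(phantom$gain),
                          phantom$grid_um)
  phantom$gain[vm > 0] <- vessel_gain
  phantom
}

# bilinear sampling of a phantom field at micrometre coordinates
phantom_field <- function(phantom, name, x_um, y_um) {
  f <- phantom[[name]]
  px <- x_um / phantom$grid_um + 0.5
  py <- y_um / phantom$grid_um + 0.5
  if (is.character(f)) {
    f[cbind(pmin(pmax(round(px), 1), nrow(f)), pmin(pmax(round(py), 1), ncol(f)))]
  } else {
    bilinear_sample(f, px, py)
  }
}

#' Lorentzian confocal envelope (intensity domain)
#'
#' `1 / (1 + ((z - zf) / zR)^2)` with `zR` half the confocal parameter.
#'
#' @param z_um depth axis, um.
#' @param zf_um focus depth, um.
#' @param confocal_parameter_um confocal parameter (2 zR), um.
#' @return envelope values.
#' @export
confocal_envelope <- function(z_um, zf_um, confocal_parameter_um) {
  zr <- confocal_parameter_um / 2
  1 / (1 + ((z_um - zf_um) / zr)^2)
}

# Core A-line synthesizer. All lateral-field inputs are vectors over n
# A-lines; returns complex matrices [n, nz] for each channel.
# delta-n accumulates retardance in the double-pass convention.
synthesize_alines <- function(mu_s, delta_n, axis_deg, surface_um, cfg, nz,
                              confound = NULL, speckle = TRUE, noise = TRUE,
                              gain = 1) {
  n <- length(mu_s)
  z <- (seq_len(nz) - 1) * cfg$axial_pixel_um                   # depth axis, um
  zt <- outer(-surface_um, z, "+")                              # depth below surface
  intissue <- zt >= 0
  zf <- surface_um + cfg$confocal_focus_depth_um
  env <- confocal_envelope(matrix(z, n, nz, byrow = TRUE), zf, cfg$confocal_parameter_um)
  amp <- sqrt(env * exp(-2 * mu_s * pmax(zt, 0) / 1000) * gain) * intissue
  # accumulated round-trip retardance, reported scale (see header note)
  delta <- (720 / cfg$center_wavelength_um) * delta_n * pmax(zt, 0)
  resp <- sample_response(as.vector(delta), rep(axis_deg, nz))
  eV <- matrix(resp$co, n, nz) * amp
  eH <- matrix(resp$cross, n, nz) * amp
  if (speckle) {
    g <- matrix(complex(real = stats::rnorm(n * nz), imaginary = stats::rnorm(n * nz)),
                n, nz) / sqrt(2)
    eV <- eV * g; eH <- eH * g
  }
  J <- confound_jones(confound)
  cross <- J[1, 1] * eH + J[1, 2] * eV
  co <- J[2, 1] * eH + J[2, 2] * eV
  if (noise) {
    sd_q <- sqrt(10^(cfg$noise_floor_db / 10) / 2)
    co <- co + matrix(complex(real = stats::rnorm(n * nz, sd = sd_q),
                              imaginary = stats::rnorm(n * nz, sd = sd_q)), n, nz)
    cross <- cross + matrix(complex(real = stats::rnorm(n * nz, sd = sd_q),
                                    imaginary = stats::rnorm(n * nz, sd = sd_q)), n, nz)
  }
  list(co = co, cross = cross)
}

#' Simulate a homogeneous scattering slab
#'
#' Ensemble of independent speckled A-lines through a uniform slab, the
#' workhorse for attenuation- and birefringence-recovery checks.
#'
#' @param mu_s scattering coefficient, mm^-1.
#' @param delta_n birefringence.
#' @param axis_deg optic-axis orientation, degrees.
#' @param cfg an [optical_config()].
#' @param n_alines number of A-lines.
#' @param nz number of depth pixels.
#' @param surface_um surface depth below the first plane, um.
#' @param seed RNG seed.
#' @param speckle,noise logical toggles for speckle and detector noise.
#' @return a [pol_volume()] of dimension `n_alines x 1 x nz`.
#' @export
simulate_psoct_slab <- function(mu_s, delta_n = 0, axis_deg = 0, cfg = optical_config(),
                                n_alines = 400, nz = 100, surface_um = 30,
                                seed = 1, speckle = TRUE, noise = TRUE) {
  stopifnot(mu_s >= 0)
  ch <- with_seed(seed, synthesize_alines(rep(mu_s, n_alines), rep(delta_n, n_alines),
                                          rep(axis_deg, n_alines), rep(surface_um, n_alines),
                                          cfg, nz, NULL, speckle, noise))
  pol_volume(array(ch$co, c(n_alines, 1, nz)), array(ch$cross, c(n_alines, 1, nz)),
             meta = list(cfg = cfg, surface_um = surface_um, mu_s = mu_s,
                         delta_n = delta_n, axis_deg = axis_deg))
}

#' Simulate tiled PSOCT acquisition of a tissue phantom
#'
#' Applies the full Jones forward model per A-line: circular illumination,
#' double-pass sample retarder, lumped system birefringence, confocal
#' envelope, exponential attenuation, fully developed speckle and additive
#' detector noise. Lateral sampling positions include the confound's grid
#' distortion (about each tile center) and the apparent surface includes
#' the confound's field curvature, so the geometry pipeline can be scored
#' against the planted truth.
#'
#' @param phantom a [tissue_phantom()].
#' @param confound a [system_confound()] or NULL for an ideal instrument.
#' @param cfg an [optical_config()].
#' @param seed RNG seed.
#' @param tile_px tile size in pixels (default: FOV / lateral pixel).
#' @param depth_um imaging depth, um.
#' @param speckle,noise logical toggles.
#' @param offset_jitter_px uniform jitter applied to the *nominal* tile
#'   offsets handed to the stitcher (the true offsets stay exact).
#' @return a `psoct_tiles` object: list of tiles (each a [pol_volume()]
#'   with tile metadata), a tile layout tibble, the ground truth record,
#'   and the configuration.
#' @export
simulate_psoct_tiles <- function(phantom, confound = NULL, cfg = optical_config(),
                                 seed = 1, tile_px = NULL, depth_um = 300,
                                 speckle = TRUE, noise = TRUE,
                                 offset_jitter_px = 0) {
  lp <- cfg$lateral_pixel_psoct_um
  if (is.null(tile_px)) tile_px <- round(cfg$psoct_fov_um / lp)
  nz <- round(depth_um / cfg$axial_pixel_um)
  if (cfg$confocal_focus_depth_um > depth_um)
    stop("confocal focus lies outside the simulated depth range")
  ext_px <- c(round(phantom$width_um / lp), round(phantom$height_um / lp))
  step_px <- max(1, round(tile_px * (1 - cfg$overlap_fraction)))
  ntx <- max(1L, ceiling((ext_px[1] - tile_px) / step_px) + 1L)
  nty <- max(1L, ceiling((ext_px[2] - tile_px) / step_px) + 1L)
  origins <- function(n, ext) {
    o <- (seq_len(n) - 1L) * step_px
    pmin(o, max(ext - tile_px, 0L))
  }
  ox <- origins(ntx, ext_px[1]); oy <- origins(nty, ext_px[2])

  tiles <- list(); layout <- list()
  with_seed(seed, {
    for (tj in seq_len(nty)) for (ti in seq_len(ntx)) {
      u <- seq_len(tile_px); v <- seq_len(tile_px)
      g <- expand.grid(u = u, v = v)
      # grid distortion acts about the tile (FOV) center
      ctr <- c((tile_px + 1) / 2, (tile_px + 1) / 2)
      q <- if (!is.null(confound) && any(confound$grid_distortion != 0)) {
        distort_points(cbind(g$u, g$v), ctr, tile_px / 2, confound$grid_distortion)
      } else cbind(g$u, g$v)
      x_um <- (ox[ti] + q[, 1] - 0.5) * lp
      y_um <- (oy[tj] + q[, 2] - 0.5) * lp
      ms <- phantom_field(phantom, "mu_s", x_um, y_um)
      gn <- phantom_field(phantom, "gain", x_um, y_um)
      dn <- phantom_field(phantom, "delta_n", x_um, y_um)
      ax <- phantom_field(phantom, "axis_deg", x_um, y_um)
      surf <- phantom_field(phantom, "surface_um", x_um, y_um)
      if (!is.null(confound) && confound$field_curvature_um != 0) {
        rr <- (((g$u - ctr[1]) / (tile_px / 2))^2 + ((g$v - ctr[2]) / (tile_px / 2))^2) / 2
        surf <- surf + confound$field_curvature_um * rr
      }
      ch <- synthesize_alines(ms, dn, ax, surf, cfg, nz, confound, speckle, noise,
                              gain = gn)
      jit <- if (offset_jitter_px > 0) round(stats::runif(2, -offset_jitter_px, offset_jitter_px)) else c(0, 0)
      tl <- pol_volume(array(ch$co, c(tile_px, tile_px, nz)),
                       array(ch$cross, c(tile_px, tile_px, nz)),
                       meta = list(tile_i = ti, tile_j = tj,
                                   true_offset_px = c(ox[ti], oy[tj]),
                                   nominal_offset_px = c(ox[ti], oy[tj]) + jit,
                                   axial_pixel_um = cfg$axial_pixel_um,
                                   lateral_pixel_um = lp))
      tiles[[length(tiles) + 1L]] <- tl
      layout[[length(layout) + 1L]] <- tibble::tibble(
        tile = length(tiles), tile_i = ti, tile_j = tj,
        true_x = ox[ti], true_y = oy[tj],
        nominal_x = ox[ti] + jit[1], nominal_y = oy[tj] + jit[2])
    }
  })
  structure(list(tiles = tiles, layout = dplyr::bind_rows(layout),
                 phantom = phantom, confound = confound, cfg = cfg,
                 seed = seed, depth_um = depth_um, tile_px = tile_px),
            class = "psoct_tiles")
}

#' Simulate a variable-retarder calibration sample
#'
#' Single-surface reflection through the Jones chain with a retarder of the
#' given retardance and axis as the sample, used to characterize the
#' retardance and orientation estimators (dynamic-range sweeps).
#'
#' @param retardance sample retardance in degrees, `[0, 180)`.
#' @param axis sample axis in degrees, `(-90, 90]` (values outside are
#'   wrapped).
#' @param confound a [system_confound()] or NULL.
#' @param cfg an [optical_config()].
#' @param nz depth pixels; the reflection sits at `surface_index`.
#' @param surface_index depth index of the reflecting surface.
#' @return a [pol_ascan()].
#' @export
simulate_retarder_sample <- function(retardance, axis, confound = NULL,
                                     cfg = optical_config(), nz = 32,
                                     surface_index = 16) {
  stopifnot(retardance >= 0, retardance < 180)
  axis <- wrap_orientation(axis)
  resp <- sample_response(retardance, axis)
  J <- confound_jones(confound)
  e <- J %*% c(resp$cross, resp$co)          # (E_H, E_V)
  co <- cross <- complex(real = rep(0, nz))
  co[surface_index] <- e[2]; cross[surface_index] <- e[1]
  pol_ascan(co, cross, cfg$axial_pixel_um)
}

#' Simulate a mirror calibration scan
#'
#' A silver mirror has no birefringence, so any apparent retardance is the
#' system's own; this scan is the input to [calibrate_compensation()].
#'
#' @inheritParams simulate_retarder_sample
#' @export
simulate_mirror_scan <- function(confound = NULL, cfg = optical_config(),
                                 nz = 32, surface_index = 16) {
  simulate_retarder_sample(0, 0, confound, cfg, nz, surface_index)
}

#' Simulate a QWP-rotation sweep on a glass slide
#'
#' Rotating the illumination quarter-wave plate with a non-birefringent
#' sample sweeps the detected polarization state; the per-channel max/min
#' intensity over the sweep defines the polarization extinction ratio.
#'
#' @param confound a [system_confound()] or NULL.
#' @param cfg an [optical_config()].
#' @param angles QWP angles in degrees.
#' @param nz,surface_index as in [simulate_retarder_sample()].
#' @return list of [pol_ascan()], one per angle (stored as attribute
#'   `qwp_angle`).
#' @export
simulate_qwp_sweep <- function(confound = NULL, cfg = optical_config(),
                               angles = seq(0, 180, by = 3), nz = 32,
                               surface_index = 16) {
  J <- confound_jones(confound)
  lapply(angles, function(b) {
    Q <- jones_qwp(b)
    e <- J %*% (Q %*% (Q %*% c(1, 0)))
    co <- cross <- complex(real = rep(0, nz))
    co[surface_index] <- e[2]; cross[surface_index] <- e[1]
    a <- pol_ascan(co, cross, cfg$axial_pixel_um)
    attr(a, "qwp_angle") <- b
    a
  })
}

#' Simulate imaging of a calibration grid target
#'
#' A dot-grid target imaged through the distorting optics: dot centroids
#' are displaced by the radial grid distortion, and the target's top
#' surface reflection traces the field curvature along depth.
#'
#' @param confound a [system_confound()].
#' @param cfg an [optical_config()].
#' @param pitch_um dot pitch, um.
#' @param dot_sigma_um Gaussian dot radius parameter, um.
#' @param size_px image size in pixels (default: FOV / lateral pixel).
#' @param nz depth planes of the surface volume.
#' @param surface_depth_um mean depth of the target surface, um.
#' @return list with `image` (distorted dot grid), `ideal_centroids`
#'   (tibble, undistorted truth), `distorted_centroids` (tibble),
#'   `surface_volume` (3D intensity array), `true_curvature_um` (matrix),
#'   `pitch_px`.
#' @export
simulate_grid_target <- function(confound = system_confound(), cfg = optical_config(),
                                 pitch_um = 120, dot_sigma_um = 9,
                                 size_px = NULL, nz = 24, surface_depth_um = 36) {
  lp <- cfg$lateral_pixel_psoct_um
  if (is.null(size_px)) size_px <- round(cfg$psoct_fov_um / lp)
  pitch_px <- pitch_um / lp
  stopifnot(pitch_px > 2)
  margin <- pitch_px
  pos1d <- seq(margin, size_px - margin, by = pitch_px)
  ideal <- as.matrix(expand.grid(x = pos1d, y = pos1d))
  ctr <- c((size_px + 1) / 2, (size_px + 1) / 2)
  k <- if (is.null(confound)) c(0, 0) else confound$grid_distortion
  dist_pos <- distort_points(ideal, ctr, size_px / 2, k)
  inside <- dist_pos[, 1] >= 1 & dist_pos[, 1] <= size_px &
    dist_pos[, 2] >= 1 & dist_pos[, 2] <= size_px
  if (!all(inside)) {
    warning("distortion pushed ", sum(!inside), " dots outside the FOV; truncated")
    ideal <- ideal[inside, , drop = FALSE]
    dist_pos <- dist_pos[inside, , drop = FALSE]
  }
  sig <- dot_sigma_um / lp
  img <- matrix(0, size_px, size_px)
  for (kk in seq_len(nrow(dist_pos))) {
    cx <- dist_pos[kk, 1]; cy <- dist_pos[kk, 2]
    xs <- max(1, floor(cx - 4 * sig)):min(size_px, ceiling(cx + 4 * sig))
    ys <- max(1, floor(cy - 4 * sig)):min(size_px, ceiling(cy + 4 * sig))
    img[xs, ys] <- img[xs, ys] + exp(-outer((xs - cx)^2, (ys - cy)^2, "+") / (2 * sig^2))
  }
  # field-curvature surface volume: bright reflection tracing the bowl
  fc <- if (is.null(confound)) 0 else confound$field_curvature_um
  rr <- outer(((seq_len(size_px) - ctr[1]) / (size_px / 2))^2,
              ((seq_len(size_px) - ctr[2]) / (size_px / 2))^2, "+") / 2
  zsurf_um <- surface_depth_um + fc * rr
  z <- (seq_len(nz) - 1) * cfg$axial_pixel_um
  vol <- array(0, c(size_px, size_px, nz))
  for (iz in seq_len(nz)) {
    vol[, , iz] <- exp(-(z[iz] - zsurf_um)^2 / (2 * (cfg$axial_pixel_um * 0.8)^2))
  }
  list(image = img,
       ideal_centroids = tibble::tibble(x = ideal[, 1], y = ideal[, 2]),
       distorted_centroids = tibble::tibble(x = dist_pos[, 1], y = dist_pos[, 2]),
       surface_volume = vol,
       true_curvature_um = zsurf_um - mean(zsurf_um),
       pitch_px = pitch_px)
}
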