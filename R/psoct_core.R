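# Polarization processing: reflectivity, retardance, optic-axis
# orientation, software compensation of system birefringence, and the
# polarization extinction ratio.

# channels of either a pol_ascan or pol_volume, as arrays
pol_channels <- function(x) {
  if (inherits(x, "pol_ascan")) list(co = x$co, cross = x$cross)
  else if (inherits(x, "pol_volume")) list(co = x$co, cross = x$cross)
  else stop("expected a pol_ascan or pol_volume")
}

#' Reflectivity in dB
#'
#' Total backscattered power `|co|^2 + |cross|^2` expressed in dB relative
#' to the noise floor. Because the Jones chain is unitary, reflectivity is
#' independent of sample birefringence.
#'
#' @param v a [pol_volume()] or [pol_ascan()].
#' @param floor_power reference (noise-floor) power; defaults to the
#'   power corresponding to -95 dB.
#' @return array/vector of dB values; all-zero voxels are set to the floor.
#' @export
compute_reflectivity <- function(v, floor_power = 10^(-95 / 10)) {
  stopifnot(floor_power > 0)
  ch <- pol_channels(v)
  p <- Mod(ch$co)^2 + Mod(ch$cross)^2
  p[p <= 0] <- floor_power
  10 * log10(p / floor_power)
}

#' Cumulative retardance in degrees
#'
#' Amplitude-ratio estimator `atan(|cross| / |co|)`, in degrees, range
#' exactly `[0, 90]`. Voxels where both channels sit at the noise floor are
#' flagged invalid (NA).
#'
#' @param v a [pol_volume()] or [pol_ascan()] (system compensation already
#'   applied, or deliberately bypassed for "before" curves).
#' @param floor_power power below which a voxel is considered signal-free.
#' @return array of retardance values in degrees, NA where invalid.
#' @export
compute_retardance <- function(v, floor_power = 0) {
  ch <- pol_channels(v)
  ret <- rad2deg(atan2(Mod(ch$cross), Mod(ch$co)))
  if (floor_power > 0) {
    invalid <- (Mod(ch$co)^2 + Mod(ch$cross)^2) <= 2 * floor_power
    ret[invalid] <- NA_real_
  }
  ret
}

#' Optic-axis orientation in degrees
#'
#' Half-phase-difference estimator `(Arg(cross) - Arg(co)) / 2`, wrapped to
#' `(-90, 90]`. The orientation zero is the mirror-calibration convention
#' (a mirror reads 0 after compensation). Orientation is undefined where
#' the retardance is below `retardance_floor` (phase of a near-zero cross
#' channel is meaningless) and is returned as NA there.
#'
#' @param v a [pol_volume()] or [pol_ascan()].
#' @param retardance_floor validity floor in degrees (default 5).
#' @return array of orientations in degrees, NA where undefined.
#' @export
compute_orientation <- function(v, retardance_floor = 5) {
  ch <- pol_channels(v)
  th <- wrap_orientation(rad2deg(Arg(ch$cross) - Arg(ch$co)) / 2)
  ret <- rad2deg(atan2(Mod(ch$cross), Mod(ch$co)))
  th[ret < retardance_floor] <- NA_real_
  th
}

#' Compensation model for the system birefringence
#'
#' @param retardance system retardance, degrees in `[0, 90]`.
#' @param axis system axis, degrees in `(-90, 90]`.
#' @param converged logical, whether the calibration converged.
#' @param residual_cross_fraction residual cross-channel energy fraction of
#'   the calibration mirror after compensation.
#' @return a `compensation_model` with the derived Jones operator.
#' @export
compensation_model <- function(retardance, axis, converged = TRUE,
                               residual_cross_fraction = NA_real_) {
  if (retardance < 0 || retardance > 90)
    stop("compensation retardance must lie in [0, 90] degrees")
  J <- jones_retarder(retardance, wrap_orientation(axis))
  stopifnot(unitarity_error(J) < 1e-10)
  structure(list(retardance = retardance, axis = wrap_orientation(axis),
                 jones = J, converged = converged,
                 residual_cross_fraction = residual_cross_fraction),
            class = "compensation_model")
}

#' @export
print.compensation_model <- function(x, ...) {
  cat(sprintf("<compensation_model> retardance %.3f deg, axis %.3f deg%s\n",
              x$retardance, x$axis,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

# dominant (highest-power) surface state of a mirror scan, as c(E_H, E_V)
mirror_state <- function(scan) {
  ch <- pol_channels(scan)
  p <- Mod(ch$co)^2 + Mod(ch$cross)^2
  i <- which.max(p)
  v <- c(ch$cross[i], ch$co[i])
  v / sqrt(sum(Mod(v)^2))
}

# phase of the ideal (confound-free) mirror co channel
ideal_mirror_co_phase <- function() {
  r <- sample_response(0, 0)
  Arg(r$co)
}

#' Calibrate the software birefringence compensation from a mirror scan
#'
#' Software analogue of the hardware variable-retarder procedure:
#' (1) estimate the apparent retardance of a mirror (which, being
#' non-birefringent, exposes the system's own retardance), (2) seed a
#' compensator with the opposite retardance, (3) refine (retardance, axis)
#' by Nelder-Mead until the mirror's cross-channel energy stops improving.
#'
#' Minimizing mirror cross power alone leaves a one-parameter phase gauge
#' (any residual retarder diagonal in the detection basis also nulls the
#' cross channel and only shifts the orientation zero); the objective
#' therefore adds a phase-reference term that pins the compensated mirror
#' co-channel phase to the ideal mirror phase, making the true system
#' operator the unique minimizer and fixing the orientation zero.
#'
#' @param mirror_scan a [pol_ascan()] or [pol_volume()] of a mirror.
#' @param tol convergence tolerance on the objective.
#' @param max_iter maximum optimizer iterations per start.
#' @return a [compensation_model()].
#' @export
calibrate_compensation <- function(mirror_scan, tol = 1e-12, max_iter = 500) {
  v <- mirror_state(mirror_scan)
  phase_ref <- ideal_mirror_co_phase()
  objective <- function(par) {
    C <- jones_inverse(jones_retarder(par[1], par[2]))
    w <- C %*% v
    cross_frac <- Mod(w[1])^2
    dphi <- Arg(w[2]) - phase_ref
    cross_frac + (1 - cos(dphi))
  }
  # step 1: apparent mirror retardance seeds the search
  ret0 <- rad2deg(atan2(Mod(v[1]), Mod(v[2])))
  starts <- expand.grid(ret = unique(c(ret0, 2 * ret0, 45, 70)),
                        ax = c(-60, -30, 0, 30, 60))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(c(starts$ret[s], starts$ax[s]), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = tol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # canonicalize through the Jones decomposition
  par <- best$par
  dec <- jones_to_retarder(jones_retarder(par[1], par[2]))
  ret <- dec$retardance; ax <- dec$axis
  if (ret > 90) { ret <- 180 - ret; ax <- wrap_orientation(ax + 90) }
  converged <- best$convergence == 0 && best$value < 1e-6
  if (!converged)
    warning("compensation calibration did not fully converge; returning best so far")
  C <- jones_inverse(jones_retarder(ret, ax))
  res <- Mod((C %*% v)[1])^2
  compensation_model(ret, ax, converged = converged,
                     residual_cross_fraction = res)
}

#' Apply a compensation model
#'
#' Left-multiplies every voxel's channel vector by the inverse system Jones
#' operator. Unitary: total power is preserved to numerical precision.
#'
#' @param v a [pol_volume()] or [pol_ascan()].
#' @param m a [compensation_model()].
#' @return object of the same class with compensated channels.
#' @export
apply_compensation <- function(v, m) {
  stopifnot(inherits(m, "compensation_model"))
  C <- jones_inverse(m$jones)
  ch <- pol_channels(v)
  cross <- C[1, 1] * ch$cross + C[1, 2] * ch$co
  co <- C[2, 1] * ch$cross + C[2, 2] * ch$co
  if (inherits(v, "pol_ascan")) {
    out <- pol_ascan(co, cross, v$axial_pixel_um)
  } else {
    out <- pol_volume(array(co, dim(v$co)), array(cross, dim(v$cross)), v$meta)
  }
  attr(out, "compensated") <- TRUE
  out
}

#' Polarization extinction ratio from a QWP-rotation sweep
#'
#' `PER = 10 log10(I_max / I_min)` per channel across the sweep; the surface
#' peak intensity of each scan is used. A zero minimum is clipped to the
#' noise floor and flagged.
#'
#' @param sweep list of [pol_ascan()] (e.g. from [simulate_qwp_sweep()]).
#' @param floor_power clipping floor for the minimum intensity.
#' @return tibble with one row per channel: `channel`, `per_db`,
#'   `clipped`.
#' @export
compute_per <- function(sweep, floor_power = 10^(-95 / 10)) {
  stopifnot(length(sweep) >= 2)
  peak <- function(x) max(Mod(x)^2)
  ico <- vapply(sweep, function(s) peak(s$co), numeric(1))
  icr <- vapply(sweep, function(s) peak(s$cross), numeric(1))
  one <- function(i, nm) {
    clip <- min(i) < floor_power
    tibble::tibble(channel = nm,
                   per_db = 10 * log10(max(i) / max(min(i), floor_power)),
                   clipped = clip)
  }
  dplyr::bind_rows(one(ico, "co"), one(icr, "cross"))
}

#' Polarization maps from a compensated volume
#'
#' Bundles reflectivity (dB), retardance (degrees) and orientation
#' (degrees) en-face maps. The retardance-weighted orientation map of the
#' instrument's fiber-orientation rendering is available through
#' [plot_orientation_map()].
#'
#' @param v a compensated [pol_volume()].
#' @param z_range depth-index range to average (reflectivity) / take from
#'   (retardance, orientation at the deepest plane of the range).
#' @param retardance_floor orientation validity floor, degrees.
#' @param floor_power reflectivity reference power.
#' @return a `polarization_maps` object (list of matrices).
#' @export
polarization_maps <- function(v, z_range = NULL, retardance_floor = 5,
                              floor_power = 10^(-95 / 10)) {
  d <- dim(v$co)
  if (is.null(z_range)) z_range <- c(1, d[3])
  zi <- z_range[1]:z_range[2]
  refl <- compute_reflectivity(v, floor_power)
  ret <- compute_retardance(v)
  ori <- compute_orientation(v, retardance_floor)
  structure(list(
    reflectivity_db = apply(refl[, , zi, drop = FALSE], c(1, 2), mean),
    retardance_deg = ret[, , zi[length(zi)]],
    orientation_deg = ori[, , zi[length(zi)]],
    z_range = z_range), class = "polarization_maps")
}
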