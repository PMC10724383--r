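# Optical configuration and system-confound descriptions.

#' Optical configuration of the hybrid PSOCT-2PM instrument
#'
#' Captures the acquisition geometry used throughout the pipeline. Defaults
#' correspond to the instrument this package models: 1310 nm center
#' wavelength, tissue refractive index 1.4, 3 um PSOCT / 2 um 2PM lateral
#' step, 150 um confocal parameter, focus placed 50 um below the cut
#' surface, 3 mm field of view with 10% tile overlap, and 95 dB SNR
#' (noise floor at -95 dB relative to a unit reflector).
#'
#' @param center_wavelength_um center wavelength in micrometres.
#' @param tissue_index refractive index of the tissue.
#' @param axial_pixel_um axial sampling in micrometres per pixel.
#' @param lateral_pixel_psoct_um PSOCT lateral step (um/px).
#' @param lateral_pixel_2pm_um 2PM lateral step (um/px).
#' @param confocal_focus_depth_um focus depth below the tissue surface (um).
#' @param confocal_parameter_um confocal parameter (full Lorentzian width
#'   between half-maximum points of the detected envelope), um.
#' @param noise_floor_db additive noise floor in dB relative to unit signal.
#' @param psoct_fov_um PSOCT field of view per tile (um).
#' @param overlap_fraction nominal tile overlap fraction, in `[0, 0.5)`.
#' @return an `optical_config` object (validated list).
#' @export
optical_config <- function(center_wavelength_um = 1.310,
                           tissue_index = 1.4,
                           axial_pixel_um = 3,
                           lateral_pixel_psoct_um = 3,
                           lateral_pixel_2pm_um = 2,
                           confocal_focus_depth_um = 50,
                           confocal_parameter_um = 150,
                           noise_floor_db = -95,
                           psoct_fov_um = 3000,
                           overlap_fraction = 0.10) {
  cfg <- list(center_wavelength_um = center_wavelength_um,
              tissue_index = tissue_index,
              axial_pixel_um = axial_pixel_um,
              lateral_pixel_psoct_um = lateral_pixel_psoct_um,
              lateral_pixel_2pm_um = lateral_pixel_2pm_um,
              confocal_focus_depth_um = confocal_focus_depth_um,
              confocal_parameter_um = confocal_parameter_um,
              noise_floor_db = noise_floor_db,
              psoct_fov_um = psoct_fov_um,
              overlap_fraction = overlap_fraction)
  lens <- cfg[c("center_wavelength_um", "tissue_index", "axial_pixel_um",
                "lateral_pixel_psoct_um", "lateral_pixel_2pm_um",
                "confocal_parameter_um", "psoct_fov_um")]
  if (any(unlist(lens) <= 0)) stop("all lengths in optical_config must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must lie in [0, 0.5)")
  structure(cfg, class = "optical_config")
}

#' Cross-modality pixel scale factor
#'
#' Ratio of PSOCT to 2PM lateral pixel size; the analytic scale factor of
#' the PSOCT-to-2PM transform (1.5 for 3 um vs 2 um grids).
#'
#' @param cfg an [optical_config()].
#' @export
modality_scale <- function(cfg) {
  cfg$lateral_pixel_psoct_um / cfg$lateral_pixel_2pm_um
}

#' System confound description
#'
#' The instrument imperfections the pipeline has to undo: a lumped system
#' birefringence (from telescopes, dichroic and scanning mirrors) acting as
#' a constant retarder on the detected polarization state, radial grid
#' distortion, field curvature, and multiplicative shading.
#'
#' @param system_retardance system retardance in degrees, `[0, 90]`.
#'   Default 70, the background retardance level the uncompensated
#'   instrument exhibits.
#' @param system_axis system retarder axis in degrees, `(-90, 90]`.
#' @param grid_distortion radial polynomial coefficients `c(k1, k2)` of the
#'   lateral distortion `r' = r (1 + k1 rhat^2 + k2 rhat^4)` with `rhat`
#'   the radius normalized to the half field of view.
#' @param field_curvature_um peak depth offset of the focal surface at the
#'   field edge relative to center (parabolic bowl), um.
#' @param shading_amplitude fractional vignetting at the tile corner of the
#'   multiplicative shading gain field.
#' @return a `system_confound` object.
#' @export
system_confound <- function(system_retardance = 70,
                            system_axis = 25,
                            grid_distortion = c(0.03, 0),
                            field_curvature_um = 12,
                            shading_amplitude = 0.25) {
  if (system_retardance < 0 || system_retardance > 90)
    stop("system_retardance must lie in [0, 90] degrees")
  if (max(abs(grid_distortion)) > 0.2)
    stop("grid distortion this strong is not invertible over the FOV")
  structure(list(system_retardance = system_retardance,
                 system_axis = wrap_orientation(system_axis),
                 grid_distortion = grid_distortion,
                 field_curvature_um = field_curvature_um,
                 shading_amplitude = shading_amplitude),
            class = "system_confound")
}

# Jones operator of the lumped system birefringence
confound_jones <- function(confound) {
  if (is.null(confound)) return(diag(2))
  jones_retarder(confound$system_retardance, confound$system_axis)
}

# multiplicative shading gain field for an nx x ny tile
shading_gain <- function(confound, nx, ny) {
  if (is.null(confound) || confound$shading_amplitude == 0)
    return(matrix(1, nx, ny))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rr <- outer(((seq_len(nx) - cx) / (nx / 2))^2,
              ((seq_len(ny) - cy) / (ny / 2))^2, "+") / 2
  # mild asymmetry so the gain is not exactly radially symmetric
  tilt <- 0.05 * outer((seq_len(nx) - cx) / nx, rep(1, ny))
  g <- 1 - confound$shading_amplitude * rr + confound$shading_amplitude * tilt
  g / mean(g)
}

# forward radial distortion: maps true (undistorted) -> observed coords.
# pts: 2-column matrix of pixel coords; center + rmax in pixels.
distort_points <- function(pts, center, rmax, k) {
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  r2 <- (dx^2 + dy^2) / rmax^2
  f <- 1 + k[1] * r2 + if (length(k) > 1) k[2] * r2^2 else 0
  cbind(center[1] + dx * f, center[2] + dy * f)
}

# inverse distortion by fixed-point iteration
undistort_points <- function(pts, center, rmax, k, iter = 25) {
  p <- pts
  for (i in seq_len(iter)) {
    q <- distort_points(p, center, rmax, k)
    p <- p + (pts - q)
  }
  p
}
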