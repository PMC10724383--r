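# Shared fixtures: a desk-scale optical configuration and the reference
# system confound used across the suite.

test_cfg <- function(...) optical_config(psoct_fov_um = 450, ...)

test_confound <- function(retardance = 70, axis = 25, ...) {
  system_confound(system_retardance = retardance, system_axis = axis, ...)
}

# retardance estimate at the surface peak of a single scan
surface_retardance <- function(scan) {
  p <- Mod(scan$co)^2 + Mod(scan$cross)^2
  compute_retardance(scan)[which.max(p)]
}

surface_orientation <- function(scan) {
  p <- Mod(scan$co)^2 + Mod(scan$cross)^2
  compute_orientation(scan)[which.max(p)]
}

# mean intensity depth profile of a pol_volume
mean_profile <- function(v, cfg) {
  I <- apply(Mod(v$co)^2 + Mod(v$cross)^2, 3, mean)
  z <- (seq_along(I) - 1) * cfg$axial_pixel_um
  depth_profile(z, I, surface_um = v$meta$surface_um)
}
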