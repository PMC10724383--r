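# Optical-property estimation from depth profiles: scattering coefficient,
# birefringence slope, depth-attenuation normalization, projections.

#' Build a depth profile
#'
#' @param z_um depth axis (um), strictly increasing, measured from the
#'   first sampled plane.
#' @param intensity linear-scale intensity, non-negative.
#' @param retardance_deg optional cumulative retardance (degrees).
#' @param surface_um depth of the tissue surface on the same axis.
#' @return a `depth_profile` tibble.
#' @export
depth_profile <- function(z_um, intensity, retardance_deg = NULL, surface_um = 0) {
  stopifnot(all(diff(z_um) > 0), all(intensity >= 0, na.rm = TRUE))
  out <- tibble::tibble(z_um = z_um, intensity = intensity)
  if (!is.null(retardance_deg)) out$retardance_deg <- retardance_deg
  attr(out, "surface_um") <- surface_um
  class(out) <- c("depth_profile", class(out))
  out
}

# mean depth profile of a volume over a lateral bin
volume_depth_profile <- function(v, cfg, retardance = TRUE, floor_power = 0) {
  p <- pol_power(v)
  I <- apply(p, 3, mean)
  ret <- NULL
  if (retardance) {
    r <- compute_retardance(v, floor_power)
    # power-weighted mean retardance per depth plane, robust under speckle
    num <- apply(r * p, 3, sum, na.rm = TRUE)
    den <- apply(p * !is.na(r), 3, sum)
    ret <- ifelse(den > 0, num / den, NA_real_)
  }
  z <- (seq_len(dim(v$co)[3]) - 1) * cfg$axial_pixel_um
  depth_profile(z, I, ret, surface_um = v$meta$surface_um %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the scattering coefficient of a depth profile
#'
#' Nonlinear least squares of the single-scattering model with a
#' Lorentzian confocal envelope,
#' `I(z) = A / (1 + ((z - zf) / zR)^2) * exp(-2 mu_s z) + C`,
#' over the in-focus band (default 50-200 um below the surface). The
#' confocal geometry (focus depth and confocal parameter) is taken from
#' the configuration; `A` and `mu_s` are free, while the offset `C` is
#' the detector noise floor, a calibration constant rather than a free
#' parameter (fitting it free would trade off against `mu_s` over the
#' short in-focus band and inflate the variance of shallow slopes).
#'
#' @param p a [depth_profile()].
#' @param cfg an [optical_config()].
#' @param fit_band_um fit band below the surface, um.
#' @param noise_floor_power known additive offset C (linear intensity);
#'   defaults to 0, appropriate when the floor is orders of magnitude
#'   below the signal.
#' @return a `scattering_fit`: `mu_s` (mm^-1), `amplitude`, `offset`,
#'   `r_squared`, `fit_range_um`, `low_confidence` flag.
#' @export
fit_scattering <- function(p, cfg = optical_config(), fit_band_um = c(50, 200),
                           noise_floor_power = 0) {
  surf <- attr(p, "surface_um") %||% 0
  zt <- p$z_um - surf
  sel <- zt >= fit_band_um[1] & zt <= fit_band_um[2] & is.finite(p$intensity)
  if (sum(sel) < 10) stop("need at least 10 samples inside the fit band")
  z <- p$z_um[sel]; I <- p$intensity[sel] - noise_floor_power
  zf <- surf + cfg$confocal_focus_depth_um
  zr <- cfg$confocal_parameter_um / 2
  env <- 1 / (1 + ((z - zf) / zr)^2)
  if (stats::sd(I) < 1e-12 * max(mean(I), 1e-300)) {
    return(structure(list(mu_s = 0, amplitude = mean(I), offset = 0,
                          r_squared = 0, fit_range_um = fit_band_um,
                          low_confidence = TRUE), class = "scattering_fit"))
  }
  # log-slope start value (also the fallback when the nonlinear fit is
  # degenerate, e.g. a noise-free profile the model matches exactly)
  ok <- I > 0
  logfit <- stats::lm(log(I[ok] / env[ok]) ~ z[ok])
  sl <- stats::coef(logfit)[2]
  mu0 <- max(-sl[[1]] * 1000 / 2, 0)
  a0 <- exp(stats::coef(logfit)[1])
  # the mean of N speckled A-lines has sd ~ I/sqrt(N): relative weighting
  w <- 1 / pmax(I, 1e-12 * max(I))^2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ A * env * exp(-2 * mu * z / 1000),
      start = list(A = max(a0, 1e-12), mu = max(mu0, 0.05)),
      weights = w,
      lower = c(0, 0), upper = c(Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a0 <- unname(a0); mu0 <- unname(mu0)
    pred <- a0 * env * exp(-2 * mu0 * z / 1000)
    r2 <- 1 - sum((I - pred)^2) / max(sum((I - mean(I))^2), 1e-300)
    return(structure(list(mu_s = mu0, amplitude = a0,
                          offset = noise_floor_power,
                          r_squared = max(min(r2, 1), 0),
                          fit_range_um = fit_band_um,
                          low_confidence = r2 < 0.5),
                     class = "scattering_fit"))
  }
  pred <- stats::predict(fit)
  r2 <- 1 - sum((I - pred)^2) / sum((I - mean(I))^2)
  cf <- stats::coef(fit)
  structure(list(mu_s = unname(cf["mu"]), amplitude = unname(cf["A"]),
                 offset = noise_floor_power, r_squared = r2,
                 fit_range_um = fit_band_um, low_confidence = r2 < 0.5),
            class = "scattering_fit")
}

#' Fit the birefringence of a retardance depth profile
#'
#' Intensity-weighted linear fit of cumulative retardance versus depth
#' below the tissue surface, constrained through the surface (zero
#' retardance at zero depth). Depths where the accumulated retardance
#' approaches the 90-degree wrap are excluded. The slope is clipped at 0;
#' birefringence follows the double-pass convention
#' `delta_n = slope * lambda / 720` (slope in degrees/um).
#'
#' @param p a [depth_profile()] with a `retardance_deg` column.
#' @param cfg an [optical_config()] (wavelength).
#' @param fit_band_um fit band below the surface, um.
#' @param max_retardance_deg exclusion bound near the wrap (default 80).
#' @return a `birefringence_fit`: `slope_deg_mm`, `delta_n`, `r_squared`,
#'   `n_points`, `valid`.
#' @export
fit_birefringence <- function(p, cfg = optical_config(), fit_band_um = c(50, 200),
                              max_retardance_deg = 80) {
  if (is.null(p$retardance_deg)) stop("profile has no retardance")
  surf <- attr(p, "surface_um") %||% 0
  zt <- p$z_um - surf
  sel <- zt >= fit_band_um[1] & zt <= fit_band_um[2] &
    is.finite(p$retardance_deg)
  # cumulative retardance wraps at 90 degrees; everything at and beyond
  # the first approach to the wrap is excluded (folded values would
  # otherwise re-enter the fit)
  wrap_hit <- which(sel & p$retardance_deg >= max_retardance_deg)
  if (length(wrap_hit) > 0) sel[min(wrap_hit):length(sel)] <- FALSE
  if (sum(sel) < 5) {
    return(structure(list(slope_deg_mm = NA_real_, delta_n = NA_real_,
                          r_squared = NA_real_, n_points = sum(sel),
                          valid = FALSE), class = "birefringence_fit"))
  }
  z <- zt[sel]; r <- p$retardance_deg[sel]
  w <- if (!is.null(p$intensity)) p$intensity[sel] else rep(1, sum(sel))
  fit <- stats::lm(r ~ 0 + z, weights = w)
  slope <- max(unname(stats::coef(fit)[1]), 0)       # deg per um
  ssr <- sum(w * stats::residuals(fit)^2)
  sst <- sum(w * (r - stats::weighted.mean(r, w))^2)
  structure(list(slope_deg_mm = slope * 1000,
                 delta_n = slope * cfg$center_wavelength_um / 720,
                 r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
                 n_points = sum(sel), valid = TRUE),
            class = "birefringence_fit")
}

#' Fit optical properties over a lateral grid of bins
#'
#' Splits a volume into `bin_px x bin_px` lateral bins (speckle
#' averaging), extracts the mean depth profile of each and fits scattering
#' and birefringence. This is how per-slice property maps and region
#' summaries are produced.
#'
#' @param v a compensated [pol_volume()].
#' @param cfg an [optical_config()].
#' @param bin_px lateral bin size in pixels (default 20).
#' @param fit_band_um fit band below the surface, um.
#' @return tibble with one row per bin: bin centers (px), `mu_s`,
#'   `r_squared_mu`, `slope_deg_mm`, `delta_n`, `r_squared_bir`.
#' @export
fit_property_maps <- function(v, cfg = optical_config(), bin_px = 20,
                              fit_band_um = c(50, 200)) {
  d <- dim(v$co)
  nbx <- max(1, floor(d[1] / bin_px)); nby <- max(1, floor(d[2] / bin_px))
  rows <- list()
  for (bx in seq_len(nbx)) for (by in seq_len(nby)) {
    xs <- ((bx - 1) * bin_px + 1):min(bx * bin_px, d[1])
    ys <- ((by - 1) * bin_px + 1):min(by * bin_px, d[2])
    sub <- pol_volume(v$co[xs, ys, , drop = FALSE], v$cross[xs, ys, , drop = FALSE],
                      v$meta)
    prof <- volume_depth_profile(sub, cfg)
    sf <- tryCatch(fit_scattering(prof, cfg, fit_band_um), error = function(e) NULL)
    bf <- fit_birefringence(prof, cfg, fit_band_um)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      bin_x = mean(xs), bin_y = mean(ys),
      mu_s = if (is.null(sf)) NA_real_ else sf$mu_s,
      r_squared_mu = if (is.null(sf)) NA_real_ else sf$r_squared,
      slope_deg_mm = bf$slope_deg_mm, delta_n = bf$delta_n,
      r_squared_bir = bf$r_squared)
  }
  dplyr::bind_rows(rows)
}

#' Depth-attenuation normalization of an intensity volume
#'
#' For each XY frame: divide by a Gaussian-smoothed version of itself
#' (retrospective high-pass that removes lateral intensity variation,
#' preserving within-frame contrast ratios), then rescale so every frame
#' has the same mean. Frames with (near) zero mean are left untouched and
#' flagged.
#'
#' @param v 3D numeric array `[x, y, z]`.
#' @param sigma_px Gaussian sigma of the background estimate (px).
#' @return list: `volume` (normalized array), `skipped` (integer vector of
#'   skipped frame indices).
#' @export
depth_attenuation_normalize <- function(v, sigma_px = 20) {
  stopifnot(length(dim(v)) == 3)
  out <- v
  skipped <- integer(0)
  mu <- apply(v, 3, mean)
  target <- mean(mu[mu > 0])
  for (iz in seq_len(dim(v)[3])) {
    f <- v[, , iz]
    m <- mean(f)
    if (!is.finite(m) || m <= 1e-12 * max(abs(f), 1)) {
      skipped <- c(skipped, iz); next
    }
    bg <- gauss_blur(f, sigma_px)
    bg[bg <= 0] <- m
    hp <- f / bg
    out[, , iz] <- hp * target / mean(hp)
  }
  list(volume = out, skipped = skipped)
}

#' Depth projection of a volume
#'
#' @param v 3D numeric array `[x, y, z]`.
#' @param kind `"AIP"` (mean), `"MIP"` (max) or `"minIP"` (min).
#' @param z_range inclusive depth-index range; default all.
#' @return projection matrix.
#' @export
project <- function(v, kind = c("AIP", "MIP", "minIP"), z_range = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(dim(v)) == 3)
  if (is.null(z_range)) z_range <- c(1, dim(v)[3])
  if (z_range[1] > z_range[2] || z_range[1] < 1 || z_range[2] > dim(v)[3])
    stop("empty or out-of-bounds z range")
  sub <- v[, , z_range[1]:z_range[2], drop = FALSE]
  f <- switch(kind, AIP = mean, MIP = max, minIP = min)
  apply(sub, c(1, 2), f)
}
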