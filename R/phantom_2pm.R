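# Two-photon autofluorescence phantom: lipofuscin granules, dark cell
# bodies, vessels, background and shading, with full ground truth.

#' Fluorophore phantom for the two-photon channels
#'
#' Samples granule, cell and vessel populations over the phantom extent.
#' The long-wavelength channel carries bright lipofuscin granules and
#' bright (blood-filled) vessels on a smooth background; the
#' short-wavelength channel carries dark cell-body silhouettes and dark
#' (empty) vessels. Densities and radii default to values typical of
#' autofluorescence imaging of aged human cortex: granules a few
#' micrometres in radius at several hundred per mm^2, soma-scale dark
#' spots around 8 um radius.
#'
#' @param width_um,height_um lateral extent, um.
#' @param granule_density_mm2 granules per mm^2.
#' @param granule_radius_meanlog,granule_radius_sdlog lognormal parameters
#'   of granule radius (um).
#' @param granule_contrast mean brightness of a granule relative to
#'   background (multiple of background level).
#' @param cell_density_mm2 dark cell bodies per mm^2.
#' @param cell_radius_um mean cell radius (um); radii are drawn +-20%.
#' @param cell_contrast fractional dimming at a cell center (0..1).
#' @param granules_per_cell mean number of perinuclear granules planted in
#'   a ring just outside each soma (lipofuscin accumulates in lysosomes
#'   around the cell body); the density above governs the scattered
#'   background population.
#' @param granule_min_separation_um minimum center separation of the
#'   scattered granules (distinct lysosomal bodies; coincident granules
#'   would be unresolvable and are not planted).
#' @param n_vessels number of vessel centerlines.
#' @param vessel_radius_um range of vessel radii (um).
#' @param seed RNG seed.
#' @return a `fluorophore_phantom` object with component tables
#'   (`granules`, `cells`, `vessels`) in micrometre coordinates and the
#'   generating parameters recorded for recovery tests.
#' @export
fluorophore_phantom <- function(width_um = 600, height_um = 600,
                                granule_density_mm2 = 400,
                                granule_radius_meanlog = log(2.5),
                                granule_radius_sdlog = 0.25,
                                granule_contrast = 2.5,
                                cell_density_mm2 = 120,
                                cell_radius_um = 8,
                                cell_contrast = 0.5,
                                granules_per_cell = 2,
                                granule_min_separation_um = 12,
                                n_vessels = 2,
                                vessel_radius_um = c(5, 18),
                                seed = 1) {
  area_mm2 <- width_um * height_um / 1e6
  with_seed(seed, {
    nc <- stats::rpois(1, cell_density_mm2 * area_mm2)
    # somata do not interpenetrate: sequential rejection keeps centers at
    # least 1.5 radii apart
    min_sep <- 1.5 * cell_radius_um
    cx <- cy <- numeric(0)
    attempts <- 0
    while (length(cx) < nc && attempts < 50 * max(nc, 1)) {
      attempts <- attempts + 1
      px <- stats::runif(1, 0, width_um); py <- stats::runif(1, 0, height_um)
      if (length(cx) == 0 || min((cx - px)^2 + (cy - py)^2) >= min_sep^2) {
        cx <- c(cx, px); cy <- c(cy, py)
      }
    }
    nc <- length(cx)
    cells <- tibble::tibble(
      id = seq_len(nc),
      x_um = cx,
      y_um = cy,
      r_um = cell_radius_um * stats::runif(nc, 0.8, 1.2))
    # scattered background granules plus perinuclear granules ringing
    # each soma (lipofuscin sits in lysosomes around the cell body)
    ng <- stats::rpois(1, granule_density_mm2 * area_mm2)
    # dart throwing keeps the planted count while spacing the granules
    gx <- gy <- numeric(0)
    gattempts <- 0
    while (length(gx) < ng && gattempts < 100 * max(ng, 1)) {
      gattempts <- gattempts + 1
      px <- stats::runif(1, 0, width_um); py <- stats::runif(1, 0, height_um)
      if (length(gx) == 0 ||
          min((gx - px)^2 + (gy - py)^2) >= granule_min_separation_um^2) {
        gx <- c(gx, px); gy <- c(gy, py)
      }
    }
    ng <- length(gx)
    near_cell <- rep(NA_integer_, ng)
    if (nc > 0 && granules_per_cell > 0) {
      # every soma carries at least one granule (the cells this phantom
      # plants are the lipofuscin-filled kind the detector targets)
      per <- 1L + stats::rpois(nc, max(granules_per_cell - 1, 0))
      for (ci in seq_len(nc)) {
        if (per[ci] == 0) next
        ang <- stats::runif(per[ci], 0, 2 * pi)
        rad <- cells$r_um[ci] + stats::runif(per[ci], 0.5, 5)
        gx <- c(gx, cells$x_um[ci] + rad * cos(ang))
        gy <- c(gy, cells$y_um[ci] + rad * sin(ang))
        near_cell <- c(near_cell, rep(cells$id[ci], per[ci]))
      }
    }
    keep <- gx >= 0 & gx <= width_um & gy >= 0 & gy <= height_um
    gx <- gx[keep]; gy <- gy[keep]; near_cell <- near_cell[keep]
    ngt <- length(gx)
    granules <- tibble::tibble(
      id = seq_len(ngt),
      x_um = gx, y_um = gy,
      r_um = pmin(pmax(stats::rlnorm(ngt, granule_radius_meanlog, granule_radius_sdlog), 2), 8),
      brightness = granule_contrast * stats::runif(ngt, 0.8, 1.3),
      near_cell = near_cell)
    vessels <- lapply(seq_len(n_vessels), function(i) {
      npt <- 12
      start <- c(stats::runif(1, 0, width_um), stats::runif(1, 0, height_um))
      ang <- stats::runif(1, 0, 2 * pi)
      step <- max(width_um, height_um) / npt
      pts <- matrix(NA_real_, npt, 2); pts[1, ] <- start
      for (p in 2:npt) {
        ang <- ang + stats::rnorm(1, 0, 0.25)
        pts[p, ] <- pts[p - 1, ] + step * c(cos(ang), sin(ang))
      }
      list(path_um = pts,
           r_um = stats::runif(1, vessel_radius_um[1], vessel_radius_um[2]),
           polarity = if (i %% 2 == 1) "bright" else "dark")
    })
    structure(list(width_um = width_um, height_um = height_um,
                   granules = granules, cells = cells, vessels = vessels,
                   params = list(granule_density_mm2 = granule_density_mm2,
                                 granule_radius_meanlog = granule_radius_meanlog,
                                 granule_radius_sdlog = granule_radius_sdlog,
                                 cell_density_mm2 = cell_density_mm2,
                                 cell_radius_um = cell_radius_um,
                                 cell_contrast = cell_contrast,
                                 granule_contrast = granule_contrast),
                   seed = seed),
              class = "fluorophore_phantom")
  })
}

# rasterize a vessel centerline as a tube mask on a pixel grid
rasterize_vessels <- function(vessels, nx, ny, pixel_um, origin_um = c(0, 0),
                              polarity = NULL) {
  mask <- matrix(0, nx, ny)
  for (v in vessels) {
    if (!is.null(polarity) && v$polarity != polarity) next
    pts <- v$path_um
    for (s in seq_len(nrow(pts) - 1)) {
      seg <- pts[s + 1, ] - pts[s, ]
      len <- sqrt(sum(seg^2))
      nstep <- max(2, ceiling(len / (pixel_um / 2)))
      tt <- seq(0, 1, length.out = nstep)
      cx <- (pts[s, 1] + tt * seg[1] - origin_um[1]) / pixel_um + 0.5
      cy <- (pts[s, 2] + tt * seg[2] - origin_um[2]) / pixel_um + 0.5
      keep <- cx > -v$r_um / pixel_um & cx < nx + v$r_um / pixel_um &
        cy > -v$r_um / pixel_um & cy < ny + v$r_um / pixel_um
      if (!any(keep)) next
      mask <- draw_disks(nx, ny, cx[keep], cy[keep],
                         rep(v$r_um / pixel_um, sum(keep)), 1, img = mask)
    }
  }
  mask
}

# render the two channels + truth for one tile footprint
render_2pm_tile <- function(fl, nx, ny, pixel_um, origin_um, background,
                            gain, noise_sd, bg_field) {
  gx <- (fl$granules$x_um - origin_um[1]) / pixel_um + 0.5
  gy <- (fl$granules$y_um - origin_um[2]) / pixel_um + 0.5
  gr <- fl$granules$r_um / pixel_um
  vis <- gx > -gr & gx < nx + gr & gy > -gr & gy < ny + gr
  granule_lab <- matrix(0L, nx, ny)
  granule_add <- matrix(0, nx, ny)
  for (k in which(vis)) {
    granule_lab <- draw_disks(nx, ny, gx[k], gy[k], gr[k], fl$granules$id[k],
                              img = granule_lab)
    granule_add <- draw_disks(nx, ny, gx[k], gy[k], gr[k],
                              fl$granules$brightness[k] * background,
                              img = granule_add)
  }
  cx <- (fl$cells$x_um - origin_um[1]) / pixel_um + 0.5
  cy <- (fl$cells$y_um - origin_um[2]) / pixel_um + 0.5
  cr <- fl$cells$r_um / pixel_um
  cvis <- cx > -cr & cx < nx + cr & cy > -cr & cy < ny + cr
  cell_mask <- draw_disks(nx, ny, cx[cvis], cy[cvis], cr[cvis], 1)
  bright_ves <- rasterize_vessels(fl$vessels, nx, ny, pixel_um, origin_um, "bright")
  dark_ves <- rasterize_vessels(fl$vessels, nx, ny, pixel_um, origin_um, "dark")
  p <- fl$params
  long <- gain * (background * bg_field + granule_add +
                    0.8 * background * bright_ves - 0.3 * background * dark_ves)
  short <- gain * background * bg_field *
    (1 - p$cell_contrast * cell_mask) * (1 - 0.5 * dark_ves) * (1 + 0.5 * bright_ves)
  if (noise_sd > 0) {
    long <- long + matrix(stats::rnorm(nx * ny, sd = noise_sd * background), nx, ny)
    short <- short + matrix(stats::rnorm(nx * ny, sd = noise_sd * background), nx, ny)
  }
  list(long = long, short = short,
       truth = list(granule_labels = granule_lab,
                    cell_mask = cell_mask,
                    vessel_mask = (bright_ves + dark_ves) > 0))
}

#' Simulate tiled two-photon acquisition of a fluorophore phantom
#'
#' @param fl a [fluorophore_phantom()].
#' @param cfg an [optical_config()].
#' @param seed RNG seed.
#' @param tile_px tile size in pixels (default FOV / 2PM pixel).
#' @param background mean background intensity (arbitrary units).
#' @param noise_sd additive noise standard deviation relative to background.
#' @param confound a [system_confound()] providing the shading gain, or
#'   NULL for an ideal (shading-free) instrument.
#' @return a `tpm_tiles` object: per-tile long/short channel images,
#'   per-tile ground-truth masks, the tile layout, and the shading gain.
#' @export
simulate_2pm_tiles <- function(fl, cfg = optical_config(), seed = 1,
                               tile_px = NULL, background = 100,
                               noise_sd = 0.02, confound = NULL) {
  lp <- cfg$lateral_pixel_2pm_um
  if (is.null(tile_px)) tile_px <- round(cfg$psoct_fov_um / lp)
  ext_px <- c(round(fl$width_um / lp), round(fl$height_um / lp))
  step_px <- max(1, round(tile_px * (1 - cfg$overlap_fraction)))
  ntx <- max(1L, ceiling((ext_px[1] - tile_px) / step_px) + 1L)
  nty <- max(1L, ceiling((ext_px[2] - tile_px) / step_px) + 1L)
  if ((ntx - 1) * step_px + tile_px < ext_px[1] || (nty - 1) * step_px + tile_px < ext_px[2])
    stop("tile grid does not cover the phantom extent")
  origins <- function(n, ext) pmin((seq_len(n) - 1L) * step_px, max(ext - tile_px, 0L))
  ox <- origins(ntx, ext_px[1]); oy <- origins(nty, ext_px[2])
  gain <- if (is.null(confound)) matrix(1, tile_px, tile_px) else
    shading_gain(confound, tile_px, tile_px)
  tiles <- list(); layout <- list()
  with_seed(seed, {
    # one smooth background field over the whole extent (tissue property)
    big_bg <- 1 + 0.15 * gauss_blur(matrix(stats::rnorm(ext_px[1] * ext_px[2]),
                                           ext_px[1], ext_px[2]),
                                    sigma = 40) * 8
    for (tj in seq_len(nty)) for (ti in seq_len(ntx)) {
      xs <- ox[ti] + seq_len(tile_px); ys <- oy[tj] + seq_len(tile_px)
      xs <- pmin(xs, ext_px[1]); ys <- pmin(ys, ext_px[2])
      bg_field <- big_bg[xs, ys]
      r <- render_2pm_tile(fl, tile_px, tile_px, lp,
                           origin_um = c(ox[ti], oy[tj]) * lp,
                           background = background, gain = gain,
                           noise_sd = noise_sd, bg_field = bg_field)
      tiles[[length(tiles) + 1L]] <- c(r, list(tile_i = ti, tile_j = tj,
                                               offset_px = c(ox[ti], oy[tj])))
      layout[[length(layout) + 1L]] <- tibble::tibble(
        tile = length(tiles), tile_i = ti, tile_j = tj,
        true_x = ox[ti], true_y = oy[tj],
        nominal_x = ox[ti], nominal_y = oy[tj])
    }
  })
  structure(list(tiles = tiles, layout = dplyr::bind_rows(layout),
                 phantom = fl, cfg = cfg, seed = seed,
                 shading_gain = gain, tile_px = tile_px,
                 background = background),
            class = "tpm_tiles")
}
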