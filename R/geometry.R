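# Geometric pipeline: field-curvature flattening, grid-distortion
# unwarping, retrospective shading correction, tile stitching with global
# coordinate optimization, cross-modality registration, and serial-slice
# volume assembly.

#' Estimate the field-curvature look-up table from a surface volume
#'
#' Finds the depth of the top-surface reflection per (x, y) by argmax with
#' sub-pixel parabolic refinement, smooths it, and returns the zero-mean
#' curvature LUT. Applying the LUT shifts every A-line so the surface is
#' flat.
#'
#' @param vol 3D intensity array `[x, y, z]` with a visible surface.
#' @param axial_pixel_um axial sampling (um/px).
#' @param smooth_sigma_px lateral smoothing of the depth map (px).
#' @param min_peak_fraction reject if the surface peak is below this
#'   fraction of the volume maximum in more than 5% of pixels.
#' @return a `curvature_lut`: `offset_um` (zero-mean matrix),
#'   `offset_px`, `axial_pixel_um`.
#' @export
estimate_field_curvature <- function(vol, axial_pixel_um = 3,
                                     smooth_sigma_px = 3,
                                     min_peak_fraction = 0.1) {
  stopifnot(length(dim(vol)) == 3)
  d <- dim(vol)
  peak_val <- apply(vol, c(1, 2), max)
  if (mean(peak_val < min_peak_fraction * max(vol)) > 0.05)
    stop("surface not detected in more than 5% of pixels")
  iz <- apply(vol, c(1, 2), which.max)
  # parabolic sub-pixel refinement around the discrete argmax
  frac <- matrix(0, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    i <- iz[x, y]
    if (i > 1 && i < d[3]) {
      ym <- vol[x, y, i - 1]; y0 <- vol[x, y, i]; yp <- vol[x, y, i + 1]
      den <- ym - 2 * y0 + yp
      if (den < 0) frac[x, y] <- 0.5 * (ym - yp) / den
    }
  }
  zmap <- (iz - 1 + frac) * axial_pixel_um
  zmap <- gauss_blur(zmap, smooth_sigma_px)
  off <- zmap - mean(zmap)
  structure(list(offset_um = off, offset_px = off / axial_pixel_um,
                 axial_pixel_um = axial_pixel_um),
            class = "curvature_lut")
}

#' Flatten a volume with a curvature LUT
#'
#' Shifts each A-line axially by the (rounded) LUT offset so the surface
#' becomes flat. Flattening is not idempotent, so the result carries a
#' `flattened` flag and re-flattening an already flattened volume is an
#' error.
#'
#' @param vol 3D array or [pol_volume()].
#' @param lut a `curvature_lut` from [estimate_field_curvature()].
#' @return same type as `vol`, flattened, with attribute `flattened`.
#' @export
flatten_volume <- function(vol, lut) {
  if (isTRUE(attr(vol, "flattened")))
    stop("volume is already flattened; applying the LUT twice would corrupt it")
  shift_arr <- function(a) {
    d <- dim(a)
    out <- array(a[1] * 0, d)
    sh <- round(lut$offset_px)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
      s <- sh[x, y]
      src <- (1 + max(s, 0)):(d[3] + min(s, 0))
      out[x, y, src - s] <- a[x, y, src]
    }
    out
  }
  if (inherits(vol, "pol_volume")) {
    out <- pol_volume(shift_arr(vol$co), shift_arr(vol$cross), vol$meta)
  } else {
    out <- shift_arr(vol)
  }
  attr(out, "flattened") <- TRUE
  out
}

#' Estimate the grid unwarp field from a distorted grid-target image
#'
#' Detects dot centroids, assigns each to the nearest node of the ideal
#' lattice (generated with the same pitch and orientation), and fits a
#' smooth polynomial displacement field mapping ideal to distorted
#' coordinates. Inverting the field unwarps sample images.
#'
#' @param img distorted grid image (matrix).
#' @param pitch_px lattice pitch in pixels.
#' @param degree polynomial degree of the displacement model (default 3,
#'   which represents a cubic radial distortion exactly).
#' @param threshold_fraction dot detection threshold as a fraction of the
#'   image maximum.
#' @return a `warp_field`: control-point pairs, fitted models, and the
#'   mean-residual diagnostics.
#' @export
estimate_grid_unwarp <- function(img, pitch_px, degree = 3,
                                 threshold_fraction = 0.3) {
  lab <- label_components(img > threshold_fraction * max(img))
  st <- component_stats(lab, weights = img)
  if (nrow(st) < 25) stop("need at least 25 detected grid dots, got ", nrow(st))
  # lattice registration: modular offset first, then re-anchor the lattice
  # phase on the most central dots, where radial distortion vanishes
  off_x <- stats::median(st$cx %% pitch_px)
  off_y <- stats::median(st$cy %% pitch_px)
  ctr <- c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
  for (pass in 1:2) {
    ix <- round((st$cx - off_x) / pitch_px)
    iy <- round((st$cy - off_y) / pitch_px)
    r2 <- (st$cx - ctr[1])^2 + (st$cy - ctr[2])^2
    central <- order(r2)[seq_len(min(4, nrow(st)))]
    off_x <- off_x + mean(st$cx[central] - (off_x + ix[central] * pitch_px))
    off_y <- off_y + mean(st$cy[central] - (off_y + iy[central] * pitch_px))
  }
  ideal_x <- off_x + ix * pitch_px
  ideal_y <- off_y + iy * pitch_px
  disp <- sqrt((st$cx - ideal_x)^2 + (st$cy - ideal_y)^2)
  if (any(disp > pitch_px / 2))
    stop("ambiguous lattice assignment: displacement exceeds half a pitch")
  cp <- tibble::tibble(ideal_x, ideal_y, dist_x = st$cx, dist_y = st$cy)
  fit_x <- stats::lm(dist_x ~ stats::poly(ideal_x, ideal_y, degree = degree, raw = TRUE),
                     data = cp)
  fit_y <- stats::lm(dist_y ~ stats::poly(ideal_x, ideal_y, degree = degree, raw = TRUE),
                     data = cp)
  res <- sqrt(mean(stats::residuals(fit_x)^2 + stats::residuals(fit_y)^2))
  structure(list(control_points = cp, fit_x = fit_x, fit_y = fit_y,
                 degree = degree, rms_residual_px = res),
            class = "warp_field")
}

#' Map points through a warp field
#'
#' @param warp a `warp_field`.
#' @param pts 2-column matrix of pixel coordinates.
#' @param direction `"forward"` maps ideal -> distorted; `"inverse"` maps
#'   distorted -> ideal (fixed-point iteration).
#' @return 2-column matrix of mapped coordinates.
#' @export
warp_points <- function(warp, pts, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  fwd <- function(p) {
    nd <- data.frame(ideal_x = p[, 1], ideal_y = p[, 2])
    cbind(stats::predict(warp$fit_x, nd), stats::predict(warp$fit_y, nd))
  }
  if (direction == "forward") return(fwd(pts))
  p <- pts
  for (i in 1:30) p <- p + (pts - fwd(p))
  p
}

#' Unwarp an image with a warp field
#'
#' Resamples the distorted image onto the ideal grid: each output pixel
#' takes the bilinear sample at its forward-warped (distorted) location,
#' scaled by the local area Jacobian of the warp so that total image mass
#' is preserved under the resampling.
#'
#' @param img distorted image.
#' @param warp a `warp_field`.
#' @return unwarped image of the same size.
#' @export
apply_unwarp <- function(img, warp) {
  g <- as.matrix(expand.grid(x = seq_len(nrow(img)), y = seq_len(ncol(img))))
  q <- warp_points(warp, g, "forward")
  # area Jacobian det by central differences of the forward map
  h <- 0.5
  qx1 <- warp_points(warp, g + cbind(rep(h, nrow(g)), 0), "forward")
  qx0 <- warp_points(warp, g - cbind(rep(h, nrow(g)), 0), "forward")
  qy1 <- warp_points(warp, g + cbind(0, rep(h, nrow(g))), "forward")
  qy0 <- warp_points(warp, g - cbind(0, rep(h, nrow(g))), "forward")
  jac <- ((qx1[, 1] - qx0[, 1]) * (qy1[, 2] - qy0[, 2]) -
            (qx1[, 2] - qx0[, 2]) * (qy1[, 1] - qy0[, 1])) / (2 * h)^2
  matrix(bilinear_sample(img, q[, 1], q[, 2]) * jac, nrow(img), ncol(img))
}

#' Retrospective flat-field (shading) correction
#'
#' Estimates the multiplicative shading gain as a smooth (low-order
#' polynomial) surface fitted to the per-pixel median across tiles,
#' normalized to mean 1, and divides every tile by it. A robust stand-in
#' for retrospective flat-fielding of mosaic microscopy; requires enough
#' tiles for the median to suppress sample structure. The polynomial
#' surface avoids the boundary bias a kernel smoother would introduce at
#' tile edges.
#'
#' @param tiles list of equally sized matrices.
#' @param degree polynomial degree of the gain surface (default 4).
#' @param min_tiles minimum number of tiles (default 20); with fewer a
#'   unity gain is returned with a warning.
#' @return list: `gain` matrix, `tiles` (corrected), `fallback` flag.
#' @export
correct_shading <- function(tiles, degree = 4, min_tiles = 20) {
  stopifnot(length(tiles) >= 1)
  d <- dim(tiles[[1]])
  if (length(tiles) < min_tiles) {
    warning("fewer than ", min_tiles, " tiles; falling back to unity gain")
    return(list(gain = matrix(1, d[1], d[2]), tiles = tiles, fallback = TRUE))
  }
  stk <- array(unlist(tiles), c(d[1], d[2], length(tiles)))
  med <- apply(stk, c(1, 2), stats::median)
  g <- expand.grid(x = seq_len(d[1]) / d[1] - 0.5, y = seq_len(d[2]) / d[2] - 0.5)
  fit <- stats::lm(z ~ stats::poly(x, y, degree = degree, raw = TRUE),
                   data = cbind(g, z = as.vector(med)))
  gain <- matrix(stats::predict(fit), d[1], d[2])
  gain <- gain / mean(gain)
  gain[gain < 0.05] <- 0.05
  list(gain = gain, tiles = lapply(tiles, function(t) t / gain), fallback = FALSE)
}

#' Phase correlation between two equally sized images
#'
#' Returns the integer translation `shift` (how far `b` is displaced
#' relative to `a`) and the normalized correlation peak height.
#'
#' @param a,b matrices of identical size.
#' @param max_shift optional cap on the recoverable shift magnitude.
#' @return list: `shift` (c(dx, dy)), `score`.
#' @export
phase_correlation <- function(a, b, max_shift = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  A <- stats::fft(a - mean(a)); B <- stats::fft(b - mean(b))
  R <- A * Conj(B)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  if (!is.null(max_shift)) {
    d <- dim(r)
    ix <- c(seq_len(min(max_shift + 1, d[1])),
            seq.int(max(d[1] - max_shift + 1, 1), d[1]))
    mask <- matrix(FALSE, d[1], d[2])
    iy <- c(seq_len(min(max_shift + 1, d[2])),
            seq.int(max(d[2] - max_shift + 1, 1), d[2]))
    mask[unique(ix), unique(iy)] <- TRUE
    r[!mask] <- -Inf
  }
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  sh <- pk - 1L
  d <- dim(r)
  if (sh[1] > d[1] / 2) sh[1] <- sh[1] - d[1]
  if (sh[2] > d[2] / 2) sh[2] <- sh[2] - d[2]
  list(shift = unname(sh), score = max(r[is.finite(r)]))
}

#' Stitch tiles into a mosaic with globally optimized coordinates
#'
#' Measures pairwise offsets between neighbouring tiles by normalized
#' cross-correlation of their nominal overlap strips (summing correlation
#' evidence over up to three depth planes when tiles are 3D), then solves for global
#' tile coordinates by least squares over the tile graph with the first
#' tile anchored. Low-correlation edges are dropped from the solve.
#' Fusion uses linear (distance-ramp) blending in the overlaps.
#'
#' @param tiles list of matrices (or 3D arrays, whose planes vote jointly).
#' @param layout tibble with columns `tile`, `tile_i`, `tile_j`,
#'   `nominal_x`, `nominal_y` (pixel offsets of each tile's origin).
#' @param search_px maximum deviation from the nominal offset.
#' @param min_score minimum phase-correlation score to keep an edge.
#' @return a `tile_stitch`: `layout` (with optimized `x`, `y`), `edges`
#'   (per-edge measured offsets, scores, residuals), `mosaic`.
#' @export
stitch_tiles <- function(tiles, layout, search_px = 10, min_score = 0.2) {
  n <- length(tiles)
  stopifnot(nrow(layout) == n)
  planes_of <- function(t) {
    if (length(dim(t)) == 3) {
      nz <- dim(t)[3]
      # three interior depth bands, averaged: band means suppress the
      # per-plane speckle while keeping independent evidence per band
      edges <- round(nz * c(0.15, 0.4, 0.65, 0.9))
      lapply(1:3, function(b) {
        zi <- max(1, edges[b] + 1):max(edges[b + 1], edges[b] + 1)
        apply(t[, , zi, drop = FALSE], c(1, 2), mean)
      })
    } else list(t)
  }
  d <- dim(planes_of(tiles[[1]])[[1]])
  edges <- list()
  for (e1 in seq_len(n)) for (e2 in seq_len(n)) {
    if (e2 <= e1) next
    dx <- layout$nominal_x[e2] - layout$nominal_x[e1]
    dy <- layout$nominal_y[e2] - layout$nominal_y[e1]
    # neighbours: overlapping in one axis, aligned in the other
    if (abs(dx) >= d[1] || abs(dy) >= d[2]) next
    ov_x <- d[1] - abs(dx); ov_y <- d[2] - abs(dy)
    if (ov_x <= 4 || ov_y <= 4) next
    if (ov_x < d[1] / 2 && ov_y < d[2] / 2) next   # corner contact only
    pa <- planes_of(tiles[[e1]]); pb <- planes_of(tiles[[e2]])
    # phase-correlate the nominal overlap strips: they are identical up to
    # the residual offset (true minus nominal), which must be < search_px
    ax <- max(1, dx + 1):min(d[1], d[1] + dx)
    ay <- max(1, dy + 1):min(d[2], d[2] + dy)
    bx <- ax - dx; by <- ay - dy
    racc <- NULL
    for (p in seq_along(pa)) {
      sa <- pa[[p]][ax, ay]; sb <- pb[[p]][bx, by]
      A <- stats::fft(sa - mean(sa)); B <- stats::fft(sb - mean(sb))
      r <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / length(A)
      r <- r / sqrt(sum((sa - mean(sa))^2) * sum((sb - mean(sb))^2))
      racc <- if (is.null(racc)) r else racc + r
    }
    racc <- racc / length(pa)
    dd <- dim(racc)
    wrapv <- function(i, nn) ifelse(i - 1 > nn / 2, i - 1 - nn, i - 1)
    sx <- wrapv(seq_len(dd[1]), dd[1]); sy <- wrapv(seq_len(dd[2]), dd[2])
    rwin <- racc
    rwin[!outer(abs(sx) <= search_px, abs(sy) <= search_px)] <- -Inf
    pk <- which(rwin == max(rwin), arr.ind = TRUE)[1, ]
    meas <- c(dx + sx[pk[1]], dy + sy[pk[2]])
    edges[[length(edges) + 1L]] <- tibble::tibble(
      from = e1, to = e2, nominal_dx = dx, nominal_dy = dy,
      dx = meas[1], dy = meas[2], score = max(rwin[is.finite(rwin)]))
  }
  if (length(edges) == 0) {
    edges <- tibble::tibble(from = integer(), to = integer(),
                            nominal_dx = numeric(), nominal_dy = numeric(),
                            dx = numeric(), dy = numeric(), score = numeric())
  } else {
    edges <- dplyr::bind_rows(edges)
  }
  used <- edges$score >= min_score &
    abs(edges$dx - edges$nominal_dx) <= search_px &
    abs(edges$dy - edges$nominal_dy) <= search_px
  edges$used <- used
  # global least squares per axis, anchor tile 1
  solve_axis <- function(dvec) {
    E <- edges[used, ]
    A <- matrix(0, nrow(E) + 1, n)
    b <- numeric(nrow(E) + 1)
    for (k in seq_len(nrow(E))) {
      A[k, E$from[k]] <- -1; A[k, E$to[k]] <- 1; b[k] <- dvec[k]
    }
    A[nrow(E) + 1, 1] <- 1e3
    b[nrow(E) + 1] <- 1e3 * layout$nominal_x[1] * 0   # anchor at 0-relative
    sol <- stats::lm.fit(A, b)$coefficients
    sol[is.na(sol)] <- 0
    sol
  }
  if (any(used)) {
    px <- solve_axis(edges$dx[used]) + layout$nominal_x[1]
    py <- solve_axis(edges$dy[used]) + layout$nominal_y[1]
  } else {
    px <- layout$nominal_x; py <- layout$nominal_y
  }
  layout$x <- round(px); layout$y <- round(py)
  if (nrow(edges) > 0) {
    edges$residual_dx <- edges$dx - (layout$x[edges$to] - layout$x[edges$from])
    edges$residual_dy <- edges$dy - (layout$y[edges$to] - layout$y[edges$from])
  }
  mosaic <- fuse_tiles(lapply(tiles, function(t) {
    if (length(dim(t)) == 3) apply(t, c(1, 2), mean) else t
  }), layout$x, layout$y)
  structure(list(layout = layout, edges = edges, mosaic = mosaic),
            class = "tile_stitch")
}

# linear-blend fusion of 2D tiles at integer offsets
fuse_tiles <- function(tiles, x, y) {
  d <- dim(tiles[[1]])
  x <- x - min(x); y <- y - min(y)
  W <- max(x) + d[1]; H <- max(y) + d[2]
  acc <- matrix(0, W, H); wac <- matrix(0, W, H)
  ramp <- function(nn) pmin(seq_len(nn), rev(seq_len(nn))) / (nn / 2)
  wt <- outer(ramp(d[1]), ramp(d[2]))
  for (k in seq_along(tiles)) {
    xs <- x[k] + seq_len(d[1]); ys <- y[k] + seq_len(d[2])
    acc[xs, ys] <- acc[xs, ys] + tiles[[k]] * wt
    wac[xs, ys] <- wac[xs, ys] + wt
  }
  out <- acc / pmax(wac, 1e-12)
  out[wac == 0] <- NA
  out
}

#' Cross-modality transform (PSOCT grid to 2PM grid)
#'
#' @param scale dimensionless scale factor (> 0).
#' @param shift integer pixel shift `c(dx, dy)` in 2PM pixel units.
#' @param score correlation score of the registration (diagnostic).
#' @return a `modality_transform`.
#' @export
modality_transform <- function(scale, shift = c(0, 0), score = NA_real_) {
  stopifnot(scale > 0)
  structure(list(scale = scale, shift = shift, score = score),
            class = "modality_transform")
}

#' @export
print.modality_transform <- function(x, ...) {
  cat(sprintf("<modality_transform> scale %.4g, shift (%d, %d) px\n",
              x$scale, x$shift[1], x$shift[2]))
  invisible(x)
}

# resample a PSOCT-grid image onto the 2PM grid under a transform
resample_to_2pm <- function(img, transform, nx_out, ny_out) {
  xs <- (seq_len(nx_out) - transform$shift[1] - 0.5) / transform$scale + 0.5
  ys <- (seq_len(ny_out) - transform$shift[2] - 0.5) / transform$scale + 0.5
  g <- expand.grid(x = xs, y = ys)
  matrix(bilinear_sample(img, g$x, g$y), nx_out, ny_out)
}

#' Register PSOCT to 2PM images
#'
#' The scale is fixed analytically by the pixel-size ratio (1.5 for
#' 3 um / 2 um grids); the integer shift is the argmax of the
#' cross-correlation between the rescaled PSOCT image and the 2PM image,
#' found on shared structure such as vessels.
#'
#' @param psoct_img PSOCT-grid image (matrix).
#' @param tpm_img 2PM-grid image (matrix).
#' @param cfg an [optical_config()] (pixel sizes).
#' @param max_shift_px maximum shift searched, in 2PM pixels.
#' @param min_score reject the registration below this normalized
#'   correlation peak.
#' @return a [modality_transform()].
#' @export
register_modalities <- function(psoct_img, tpm_img, cfg = optical_config(),
                                max_shift_px = 150, min_score = 0.05) {
  scale <- modality_scale(cfg)
  fix_na <- function(m) { m[!is.finite(m)] <- mean(m[is.finite(m)]); m }
  psoct_img <- fix_na(psoct_img); tpm_img <- fix_na(tpm_img)
  nx_up <- round(nrow(psoct_img) * scale); ny_up <- round(ncol(psoct_img) * scale)
  up <- resize_bilinear(psoct_img, nx_up, ny_up)
  nx <- max(nrow(up), nrow(tpm_img)) + max_shift_px
  ny <- max(ncol(up), ncol(tpm_img)) + max_shift_px
  pad <- function(m) { out <- matrix(0, nx, ny); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m - mean(m); out }
  A <- stats::fft(pad(tpm_img)); B <- stats::fft(pad(up))
  r <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / (nx * ny)
  r <- r / sqrt(sum((tpm_img - mean(tpm_img))^2) * sum((up - mean(up))^2))
  wrap <- function(i, nn) ifelse(i > nn / 2, i - nn, i)
  d <- dim(r)
  sx <- wrap(seq_len(d[1]) - 1, d[1]); sy <- wrap(seq_len(d[2]) - 1, d[2])
  ok <- outer(abs(sx) <= max_shift_px, abs(sy) <= max_shift_px)
  r[!ok] <- -Inf
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  score <- max(r[is.finite(r)])
  if (score < min_score)
    stop("registration failed: correlation peak ", signif(score, 3),
         " below threshold")
  modality_transform(scale, c(sx[pk[1]], sy[pk[2]]), score)
}

#' Compose two modality transforms
#'
#' `compose_transforms(ab, ba)` should be close to identity when `ba`
#' registers the opposite direction.
#'
#' @param t1,t2 [modality_transform()] objects.
#' @return a [modality_transform()] representing `t2 o t1`.
#' @export
compose_transforms <- function(t1, t2) {
  modality_transform(t1$scale * t2$scale, t2$scale * t1$shift + t2$shift)
}

#' Assemble a serial-section volume from per-slice in-focus bands
#'
#' Concatenates each slice's in-focus depth band at its physical Z offset
#' (the cut thickness). No Z blending: stage precision is at the
#' resolution scale, so slices abut. If the band is thinner than the cut,
#' a gap map is attached with a warning.
#'
#' @param slices list of 3D arrays (already flattened/stitched), full
#'   depth.
#' @param axial_pixel_um axial sampling (um/px).
#' @param slice_thickness_um physical cut thickness, um.
#' @param band_um in-focus band below the surface `c(lo, hi)`, um.
#' @param surface_um depth of the (flattened) surface in each slice, um.
#' @return list: `volume` (3D array), `gaps_um` (0 when gap-free),
#'   `z_offsets_um`.
#' @export
assemble_volume <- function(slices, axial_pixel_um = 3,
                            slice_thickness_um = 150,
                            band_um = c(50, 200), surface_um = 0) {
  stopifnot(length(slices) >= 1)
  band_ext <- band_um[2] - band_um[1]
  gap <- slice_thickness_um - band_ext
  if (gap > 1e-9)
    warning("in-focus band (", band_ext, " um) thinner than cut (",
            slice_thickness_um, " um): ", gap, " um gap per slice")
  i0 <- round((surface_um + band_um[1]) / axial_pixel_um) + 1
  nzb <- round(min(band_ext, slice_thickness_um) / axial_pixel_um)
  parts <- lapply(slices, function(s) {
    stopifnot(i0 + nzb - 1 <= dim(s)[3])
    s[, , i0:(i0 + nzb - 1), drop = FALSE]
  })
  d <- dim(parts[[1]])
  vol <- array(NA_real_, c(d[1], d[2], d[3] * length(parts)))
  for (k in seq_along(parts)) vol[, , (k - 1) * d[3] + seq_len(d[3])] <- parts[[k]]
  list(volume = vol, gaps_um = max(gap, 0),
       z_offsets_um = (seq_along(slices) - 1) * slice_thickness_um)
}

#' Integer down-sampling of a volume
#'
#' Block-mean down-sampling by integer factors per axis, e.g. 10x10x10
#' for rendering-scale volumes.
#'
#' @param v 3D array.
#' @param factors integer factors `c(fx, fy, fz)`.
#' @return down-sampled array.
#' @export
downsample_volume <- function(v, factors = c(10, 10, 10)) {
  d <- dim(v); f <- factors
  nd <- d %/% f
  stopifnot(all(nd >= 1))
  v <- v[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]), drop = FALSE]
  dim(v) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  apply(v, c(2, 4, 6), mean)
}
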