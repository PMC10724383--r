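# Low-level image utilities shared across the pipeline.
#
# Images follow the (x, y) matrix convention: the first array index is the
# fast (X) scan axis, the second the slow (Y) axis; origin at [1, 1]
# (top-left), physical units are always micrometres.

#' Gaussian filtering of a 2D image
#'
#' FFT-based Gaussian convolution with mirror (reflective) padding, so that
#' arbitrarily large sigma (including kernels wider than the image, as needed
#' by the 100 um granule low-pass) is handled without boundary darkening.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return filtered matrix of the same size.
#' @export
gauss_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  nx <- nrow(img); ny <- ncol(img)
  # mirror-pad up to the image size (reflection cannot exceed it)
  px <- min(nx, ceiling(3 * sigma)); py <- min(ny, ceiling(3 * sigma))
  big <- img[c(px:1, 1:nx, nx:(nx - px + 1)), c(py:1, 1:ny, ny:(ny - py + 1)), drop = FALSE]
  out <- fft_gauss_periodic(big, sigma)
  out[px + (1:nx), py + (1:ny), drop = FALSE]
}

# periodic Gaussian convolution via the frequency-domain transfer function
fft_gauss_periodic <- function(img, sigma) {
  nx <- nrow(img); ny <- ncol(img)
  fx <- c(0:(floor(nx / 2)), -(ceiling(nx / 2) - 1):-1) / nx
  fy <- c(0:(floor(ny / 2)), -(ceiling(ny / 2) - 1):-1) / ny
  gx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  gy <- exp(-2 * pi^2 * sigma^2 * fy^2)
  H <- outer(gx, gy)
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (nx * ny)
}

#' Connected components of a binary mask (8-connectivity)
#'
#' Labels foreground pixels using 8-connectivity. Implemented as a graph
#' union over foreground pixels, which is efficient for the sparse masks
#' produced by granule segmentation.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  nx <- nrow(mask)
  # map full-image linear index -> foreground vertex id
  vid <- integer(length(mask)); vid[idx] <- seq_along(idx)
  i <- ((idx - 1L) %% nx) + 1L
  j <- ((idx - 1L) %/% nx) + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    i2 <- i + d[1]; j2 <- j + d[2]
    ok <- i2 >= 1L & i2 <= nx & j2 >= 1L & j2 <= ncol(mask)
    nb <- (j2[ok] - 1L) * nx + i2[ok]
    hit <- mask[nb]
    if (any(hit)) edges <- c(edges, rbind(vid[idx[ok][hit]], vid[nb[hit]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# per-label pixel counts and intensity-weighted centroids
component_stats <- function(lab, weights = NULL) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(id = integer(), px_count = integer(),
                          cx = numeric(), cy = numeric()))
  }
  l <- lab[idx]
  nx <- nrow(lab)
  x <- ((idx - 1L) %% nx) + 1L
  y <- ((idx - 1L) %/% nx) + 1L
  w <- if (is.null(weights)) rep(1, length(idx)) else weights[idx]
  sw <- tapply(w, l, sum)
  tibble::tibble(
    id = as.integer(names(sw)),
    px_count = as.integer(tapply(rep(1L, length(idx)), l, sum)),
    cx = as.numeric(tapply(w * x, l, sum) / sw),
    cy = as.numeric(tapply(w * y, l, sum) / sw)
  )
}

#' Bilinear sampling of an image at fractional coordinates
#'
#' @param img numeric matrix.
#' @param x,y coordinate vectors (1-based pixel units). Points outside the
#'   image are clamped to the border.
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  if (nx == 1L) x0 <- rep(1, length(x))
  if (ny == 1L) y0 <- rep(1, length(y))
  dx <- x - x0; dy <- y - y0
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, ny)
  v00 <- img[cbind(x0, y0)]; v10 <- img[cbind(x1, y0)]
  v01 <- img[cbind(x0, y1)]; v11 <- img[cbind(x1, y1)]
  v00 * (1 - dx) * (1 - dy) + v10 * dx * (1 - dy) +
    v01 * (1 - dx) * dy + v11 * dx * dy
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param nx_out,ny_out output dimensions.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, nx_out, ny_out) {
  sx <- nrow(img) / nx_out; sy <- ncol(img) / ny_out
  xs <- (seq_len(nx_out) - 0.5) * sx + 0.5
  ys <- (seq_len(ny_out) - 0.5) * sy + 0.5
  g <- expand.grid(x = xs, y = ys)
  matrix(bilinear_sample(img, g$x, g$y), nx_out, ny_out)
}

# local maxima of a 2D image within a 3x3 neighbourhood, above a threshold
local_maxima_2d <- function(img, threshold = -Inf) {
  nx <- nrow(img); ny <- ncol(img)
  if (nx < 3 || ny < 3) return(cbind(x = integer(0), y = integer(0)))
  core <- img[2:(nx - 1), 2:(ny - 1)]
  is_max <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core >= img[2:(nx - 1) + di, 2:(ny - 1) + dj]
  }
  w <- which(is_max, arr.ind = TRUE)
  cbind(x = w[, 1] + 1L, y = w[, 2] + 1L)
}

#' Wrap angles into the orientation range (-90, 90] degrees
#'
#' @param theta angles in degrees.
#' @return wrapped angles.
#' @export
wrap_orientation <- function(theta) {
  w <- ((theta + 90) %% 180) - 90
  ifelse(w == -90, 90, w)
}

#' Rasterize filled disks onto a matrix
#'
#' A pixel belongs to a disk when its center lies within the radius.
#' Used by the phantom generators and handy for building test fixtures.
#'
#' @param nx,ny image size.
#' @param cx,cy disk centers (pixel units, fractional allowed).
#' @param r_px disk radii in pixels.
#' @param value values painted per disk (recycled).
#' @param img optional existing matrix to paint onto.
#' @param accumulate add instead of overwrite.
#' @return numeric matrix.
#' @export
draw_disks <- function(nx, ny, cx, cy, r_px, value = 1, img = NULL, accumulate = FALSE) {
  if (is.null(img)) img <- matrix(0, nx, ny)
  value <- rep_len(value, length(cx))
  for (k in seq_along(cx)) {
    r <- r_px[k]
    xs <- max(1L, floor(cx[k] - r)):min(nx, ceiling(cx[k] + r))
    ys <- max(1L, floor(cy[k] - r)):min(ny, ceiling(cy[k] + r))
    if (length(xs) == 0 || length(ys) == 0) next
    d2 <- outer((xs - cx[k])^2, (ys - cy[k])^2, "+")
    inside <- d2 <= r^2
    if (accumulate) {
      img[xs, ys][inside] <- img[xs, ys][inside] + value[k]
    } else {
      img[xs, ys][inside] <- value[k]
    }
  }
  img
}

# seeded RNG scope: evaluates expr with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
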