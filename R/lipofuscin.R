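# Lipofuscin granule segmentation and sliding-window morphometry from the
# long-wavelength autofluorescence channel.

#' Huang's fuzzy threshold
#'
#' Minimum-fuzziness threshold of Huang & Wang on a 256-bin histogram.
#' Computed as a diagnostic alongside the fixed ratio bound that governs
#' the granule mask.
#'
#' @param x numeric matrix or vector of intensities.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale of `x`.
#' @export
huang_threshold <- function(x, n_bins = 256) {
  v <- as.vector(x[is.finite(x)])
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1, 1), n_bins),
                nbins = n_bins)
  mids <- lo + ((seq_len(n_bins)) - 0.5) * (hi - lo) / n_bins
  w <- h * mids
  csum_h <- cumsum(h); csum_w <- cumsum(w)
  tot_h <- csum_h[n_bins]; tot_w <- csum_w[n_bins]
  best_t <- 1; best_f <- Inf
  C <- hi - lo
  for (t in seq_len(n_bins - 1)) {
    if (csum_h[t] == 0 || csum_h[t] == tot_h) next
    mu0 <- csum_w[t] / csum_h[t]
    mu1 <- (tot_w - csum_w[t]) / (tot_h - csum_h[t])
    # membership of each bin to its class, Shannon fuzziness
    mu_x <- ifelse(seq_len(n_bins) <= t,
                   1 / (1 + abs(mids - mu0) / C),
                   1 / (1 + abs(mids - mu1) / C))
    mu_x <- pmin(pmax(mu_x, 1e-12), 1 - 1e-12)
    S <- sum(h * (-mu_x * log(mu_x) - (1 - mu_x) * log(1 - mu_x)))
    if (S < best_f) { best_f <- S; best_t <- t }
  }
  lo + best_t * (hi - lo) / n_bins
}

#' Segment lipofuscin granules
#'
#' Ratio-of-Gaussian segmentation: (1) Gaussian low-pass of the image with
#' a large sigma (default 50 px, i.e. 100 um at 2 um/px), (2) divide the
#' original by the low-pass to remove low-frequency background,
#' (3) binarize the ratio at the fixed lower bound 1.22 (Huang's fuzzy
#' threshold of the ratio image is computed and reported as a diagnostic,
#' but the fixed bound governs), (4) label 8-connected components and drop
#' those below the minimum size.
#'
#' @param img shading-corrected long-wavelength channel image (matrix),
#'   2 um/px geometry by default.
#' @param sigma_px low-pass sigma in pixels.
#' @param lower_bound ratio threshold governing the mask.
#' @param min_size_px minimum granule size in pixels.
#' @param pixel_um pixel pitch, um.
#' @return a `granule_set`: `labels` (matrix), `granules` (tibble with
#'   pixel count, centroid, equivalent radius in um), and the parameters
#'   with the Huang diagnostic threshold.
#' @export
segment_granules <- function(img, sigma_px = 50, lower_bound = 1.22,
                             min_size_px = 2, pixel_um = 2) {
  stopifnot(is.matrix(img))
  lp <- gauss_blur(img, sigma_px)
  eps_guard <- any(lp <= 0)
  lp[lp <= 0] <- max(mean(img), 1e-12)
  ratio <- img / lp
  mask <- ratio >= lower_bound
  lab <- label_components(mask)
  st <- component_stats(lab, weights = img)
  keep <- st$px_count >= min_size_px
  st <- st[keep, , drop = FALSE]
  relab <- matrix(0L, nrow(lab), ncol(lab))
  if (nrow(st) > 0) {
    new_id <- integer(max(lab))
    new_id[st$id] <- seq_len(nrow(st))
    pos <- lab > 0
    relab[pos] <- new_id[lab[pos]]
    st$id <- seq_len(nrow(st))
  }
  st$r_eq_um <- pixel_um * sqrt(st$px_count / pi)
  structure(list(labels = relab, granules = st,
                 params = list(sigma_px = sigma_px, lower_bound = lower_bound,
                               min_size_px = min_size_px, pixel_um = pixel_um,
                               huang_threshold = huang_threshold(ratio),
                               eps_guard = eps_guard)),
            class = "granule_set")
}

#' @export
print.granule_set <- function(x, ...) {
  cat(sprintf("<granule_set> %d granules over %d x %d px\n",
              nrow(x$granules), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Sliding-window lipofuscin metrics
#'
#' For every window (default 100 x 100 px = 200 x 200 um, step 50 px =
#' 100 um, fully inside the image): the segmented pixel count P1 and the
#' number of granules N touching the window give
#' * area fraction (%) = 100 * P1 / window_px^2,
#' * number density (mm^-2) = N / window area,
#' * mean radius (um) = pixel_um * sqrt(P1 / (pi * N)),
#' with the radius flagged undefined (NA) where N = 0. Granules are
#' counted in every window they overlap; pixels are counted where they
#' lie.
#'
#' @param gs a [segment_granules()] result.
#' @param window_px window edge, px.
#' @param step_px window step, px.
#' @param pixel_um pixel pitch, um.
#' @return a `metric_maps` tibble: window centers (px and um), `p1`, `n`,
#'   `area_fraction_pct`, `number_density_mm2`, `mean_radius_um`.
#' @export
window_metrics <- function(gs, window_px = 100, step_px = 50, pixel_um = 2) {
  lab <- gs$labels
  nx <- nrow(lab); ny <- ncol(lab)
  if (nx < window_px || ny < window_px)
    stop("image smaller than one metric window")
  x0 <- seq(1, nx - window_px + 1, by = step_px)
  y0 <- seq(1, ny - window_px + 1, by = step_px)
  win_area_mm2 <- (window_px * pixel_um / 1000)^2
  rows <- list()
  for (wx in x0) for (wy in y0) {
    sub <- lab[wx:(wx + window_px - 1), wy:(wy + window_px - 1)]
    p1 <- sum(sub > 0)
    n <- length(unique(sub[sub > 0]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x_px = wx + (window_px - 1) / 2, y_px = wy + (window_px - 1) / 2,
      p1 = p1, n = n)
  }
  out <- dplyr::bind_rows(rows)
  out$x_um <- (out$x_px - 0.5) * pixel_um
  out$y_um <- (out$y_px - 0.5) * pixel_um
  out$area_fraction_pct <- 100 * out$p1 / window_px^2
  out$number_density_mm2 <- out$n / win_area_mm2
  out$mean_radius_um <- ifelse(out$n > 0,
                               pixel_um * sqrt(out$p1 / (pi * out$n)),
                               NA_real_)
  attr(out, "window_px") <- window_px
  attr(out, "step_px") <- step_px
  attr(out, "pixel_um") <- pixel_um
  class(out) <- c("metric_maps", class(out))
  out
}

#' Linear age regression of lipofuscin metrics
#'
#' Ordinary least squares of per-sample metric means against age, fitted
#' separately per metric and tissue class.
#'
#' @param data data frame with columns `age`, `tissue_class`, and one or
#'   more metric columns.
#' @param metrics names of the metric columns to regress.
#' @return an `age_trend` tibble: `metric`, `tissue_class`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_vs_age <- function(data,
                           metrics = c("area_fraction_pct",
                                       "number_density_mm2",
                                       "mean_radius_um")) {
  stopifnot(all(c("age", "tissue_class") %in% names(data)))
  rows <- list()
  for (m in metrics) {
    for (cl in unique(data$tissue_class)) {
      d <- data[data$tissue_class == cl & is.finite(data[[m]]), ]
      if (nrow(d) < 3)
        stop("need at least 3 samples per class for the age regression")
      fit <- stats::lm(d[[m]] ~ d$age)
      sm <- summary(fit)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = m, tissue_class = cl,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        r_squared = sm$r.squared,
        p_value = sm$coefficients[2, 4],
        n = nrow(d))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("age_trend", class(out))
  out
}
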