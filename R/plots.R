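# ggplot2 display helpers for the main result types.

# long-format tibble of a matrix image
image_tbl <- function(m, value = "value") {
  d <- dim(m)
  out <- tibble::tibble(
    x = rep(seq_len(d[1]), times = d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    v = as.vector(m))
  names(out)[3] <- value
  out
}

#' Plot an image matrix
#'
#' @param m numeric matrix (x by y).
#' @param title plot title.
#' @param legend legend label.
#' @return a ggplot object.
#' @export
plot_image <- function(m, title = NULL, legend = "value") {
  df <- image_tbl(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = legend) +
    ggplot2::labs(title = title, x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Retardance-weighted orientation map
#'
#' The standard fiber-orientation rendering: hue encodes the in-plane
#' optic-axis orientation, brightness the retardance.
#'
#' @param maps a `polarization_maps` object.
#' @return a ggplot object.
#' @export
plot_orientation_map <- function(maps) {
  ori <- maps$orientation_deg
  ret <- maps$retardance_deg
  df <- image_tbl(ori, "orientation")
  df$retardance <- as.vector(ret)
  df <- df[is.finite(df$orientation), ]
  df$hue <- (df$orientation + 90) / 180
  df$val <- pmin(df$retardance / 90, 1)
  df$col <- grDevices::hsv(df$hue, s = 1, v = df$val)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Retardance-weighted orientation",
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Depth profile with its scattering fit
#'
#' @param p a [depth_profile()].
#' @param fit optional `scattering_fit`; drawn over the data when given.
#' @param cfg an [optical_config()] (needed to draw the fit curve).
#' @return a ggplot object.
#' @export
plot_depth_profile <- function(p, fit = NULL, cfg = optical_config()) {
  g <- ggplot2::ggplot(p, ggplot2::aes(x = .data$z_um, y = .data$intensity)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::labs(x = "depth (um)", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    surf <- attr(p, "surface_um")
    if (is.null(surf)) surf <- 0
    zf <- surf + cfg$confocal_focus_depth_um
    zr <- cfg$confocal_parameter_um / 2
    zz <- seq(surf + fit$fit_range_um[1], surf + fit$fit_range_um[2],
              length.out = 100)
    pred <- fit$amplitude / (1 + ((zz - zf) / zr)^2) *
      exp(-2 * fit$mu_s * zz / 1000) + fit$offset
    g <- g + ggplot2::geom_line(
      data = tibble::tibble(z_um = zz, intensity = pred),
      color = "red")
  }
  g
}

#' @method autoplot granule_set
#' @export
autoplot.granule_set <- function(object, ...) {
  plot_image(1 * (object$labels > 0), title = sprintf(
    "%d lipofuscin granules", nrow(object$granules)), legend = "mask")
}

#' @method autoplot metric_maps
#' @export
autoplot.metric_maps <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("x_um", "y_um", "area_fraction_pct",
               "number_density_mm2", "mean_radius_um")],
    cols = c("area_fraction_pct", "number_density_mm2", "mean_radius_um"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' @method autoplot age_trend
#' @export
autoplot.age_trend <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$metric, y = .data$slope,
                               fill = .data$tissue_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "slope per year") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
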