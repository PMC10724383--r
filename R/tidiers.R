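# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy scattering_fit
#' @export
tidy.scattering_fit <- function(x, ...) {
  tibble::tibble(term = c("mu_s", "amplitude", "offset"),
                 estimate = c(x$mu_s, x$amplitude, x$offset),
                 unit = c("mm^-1", "linear", "linear"))
}

#' @method glance scattering_fit
#' @export
glance.scattering_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 fit_lo_um = x$fit_range_um[1], fit_hi_um = x$fit_range_um[2],
                 low_confidence = x$low_confidence)
}

#' @method tidy birefringence_fit
#' @export
tidy.birefringence_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "delta_n"),
                 estimate = c(x$slope_deg_mm, x$delta_n),
                 unit = c("deg/mm", "1"))
}

#' @method glance birefringence_fit
#' @export
glance.birefringence_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points,
                 valid = x$valid)
}

#' @method tidy compensation_model
#' @export
tidy.compensation_model <- function(x, ...) {
  tibble::tibble(term = c("retardance", "axis"),
                 estimate = c(x$retardance, x$axis), unit = "degrees")
}

#' @method tidy age_trend
#' @export
tidy.age_trend <- function(x, ...) tibble::as_tibble(x)

#' @method tidy granule_set
#' @export
tidy.granule_set <- function(x, ...) tibble::as_tibble(x$granules)

#' @method glance granule_set
#' @export
glance.granule_set <- function(x, ...) {
  tibble::tibble(n_granules = nrow(x$granules),
                 total_px = sum(x$granules$px_count),
                 mean_radius_um = mean(x$granules$r_eq_um),
                 huang_threshold = x$params$huang_threshold,
                 lower_bound = x$params$lower_bound)
}

#' @method tidy correspondence_report
#' @export
tidy.correspondence_report <- function(x, ...) x$pairs

#' @method glance correspondence_report
#' @export
glance.correspondence_report <- function(x, ...) {
  tibble::tibble(n_a = x$n_a, n_b = x$n_b, matched = x$matched,
                 rate_pct = x$rate_pct)
}

#' @method tidy tile_stitch
#' @export
tidy.tile_stitch <- function(x, ...) tibble::as_tibble(x$layout)

#' @method glance tile_stitch
#' @export
glance.tile_stitch <- function(x, ...) {
  e <- x$edges
  tibble::tibble(n_tiles = nrow(x$layout), n_edges = nrow(e),
                 n_used = sum(e$used),
                 max_residual_px = if (nrow(e) > 0)
                   max(abs(c(e$residual_dx[e$used], e$residual_dy[e$used], 0)))
                 else 0)
}
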