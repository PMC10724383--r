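# Containers for complex two-channel polarization data.

#' Polarization-resolved A-scan
#'
#' A single depth profile of the complex co- and cross-polarized OCT
#' signals.
#'
#' @param co,cross complex vectors of equal length (depth).
#' @param axial_pixel_um axial sampling (um/px).
#' @return a `pol_ascan` object.
#' @export
pol_ascan <- function(co, cross, axial_pixel_um = 3) {
  stopifnot(length(co) == length(cross),
            all(is.finite(Mod(co))), all(is.finite(Mod(cross))))
  structure(list(co = as.complex(co), cross = as.complex(cross),
                 axial_pixel_um = axial_pixel_um),
            class = "pol_ascan")
}

#' Polarization-resolved volume
#'
#' Complex co/cross channels as 3D arrays indexed `[x, y, z]`, z being depth.
#'
#' @param co,cross complex arrays of identical dimension (2D images are
#'   promoted to single-plane volumes).
#' @param meta named list of acquisition metadata (pixel sizes etc.).
#' @return a `pol_volume` object.
#' @export
pol_volume <- function(co, cross, meta = list()) {
  if (length(dim(co)) == 2) dim(co) <- c(dim(co), 1L)
  if (length(dim(cross)) == 2) dim(cross) <- c(dim(cross), 1L)
  stopifnot(identical(dim(co), dim(cross)))
  structure(list(co = co, cross = cross, meta = meta), class = "pol_volume")
}

#' @export
print.pol_ascan <- function(x, ...) {
  cat(sprintf("<pol_ascan> %d depth px @ %.3g um/px\n",
              length(x$co), x$axial_pixel_um))
  invisible(x)
}

#' @export
print.pol_volume <- function(x, ...) {
  d <- dim(x$co)
  cat(sprintf("<pol_volume> %d x %d x %d (X x Y x Z)\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.pol_volume <- function(x) dim(x$co)

# total detected power per voxel
pol_power <- function(v) Mod(v$co)^2 + Mod(v$cross)^2
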