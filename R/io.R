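# File interfaces: multi-page float TIFF with JSON sidecars, CSV truth
# tables. TIFF stores data rescaled to [0, 1]; the affine restore
# parameters live in the sidecar, units are always recorded.

#' Write a stack of frames as a multi-page TIFF with sidecar
#'
#' @param frames a matrix, 3D array (z as pages) or list of matrices.
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param meta named list merged into the sidecar (pixel sizes, units,
#'   seed, ...).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, meta = list()) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  norm <- lapply(frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(offset = lo, scale = scale, n_pages = length(frames),
                 dim = dim(frames[[1]])), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff_stack()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return list: `frames` (list of matrices, restored scale), `meta`
#'   (sidecar contents).
#' @export
read_tiff_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  fr <- lapply(fr, function(f) f * side$scale + side$offset)
  list(frames = fr, meta = side)
}

#' Write simulated PSOCT tiles to a directory
#'
#' One multi-page TIFF per tile and channel component (co/cross split
#' into real and imaginary parts), a JSON sidecar with the acquisition
#' geometry, and the tile layout / ground truth as CSV.
#'
#' @param x a `psoct_tiles` object from [simulate_psoct_tiles()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_psoct_tiles <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(x$tiles)) {
    t <- x$tiles[[k]]
    base <- file.path(dir, sprintf("tile_%03d", k))
    m <- list(tile = k, tile_i = t$meta$tile_i, tile_j = t$meta$tile_j,
              lateral_pixel_um = t$meta$lateral_pixel_um,
              axial_pixel_um = t$meta$axial_pixel_um,
              nominal_offset_px = t$meta$nominal_offset_px,
              seed = x$seed, units = "um")
    write_tiff_stack(Re(t$co), paste0(base, "_co_re.tif"), m)
    write_tiff_stack(Im(t$co), paste0(base, "_co_im.tif"), m)
    write_tiff_stack(Re(t$cross), paste0(base, "_cross_re.tif"), m)
    write_tiff_stack(Im(t$cross), paste0(base, "_cross_im.tif"), m)
  }
  utils::write.csv(x$layout, file.path(dir, "layout.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_tiles = length(x$tiles), tile_px = x$tile_px, seed = x$seed,
         depth_um = x$depth_um, cfg = unclass(x$cfg),
         confound = if (!is.null(x$confound)) unclass(x$confound)),
    file.path(dir, "acquisition.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read PSOCT tiles written by [write_psoct_tiles()]
#'
#' @param dir directory produced by [write_psoct_tiles()].
#' @return a `psoct_tiles`-like list (tiles, layout, cfg fields from the
#'   sidecar).
#' @export
read_psoct_tiles <- function(dir) {
  acq <- jsonlite::read_json(file.path(dir, "acquisition.json"),
                             simplifyVector = TRUE)
  layout <- tibble::as_tibble(utils::read.csv(file.path(dir, "layout.csv")))
  tiles <- lapply(seq_len(acq$n_tiles), function(k) {
    base <- file.path(dir, sprintf("tile_%03d", k))
    rd <- function(sfx) {
      fr <- read_tiff_stack(paste0(base, sfx))$frames
      array(unlist(fr), c(dim(fr[[1]]), length(fr)))
    }
    co <- rd("_co_re.tif") + 1i * rd("_co_im.tif")
    cross <- rd("_cross_re.tif") + 1i * rd("_cross_im.tif")
    m <- read_tiff_stack(paste0(base, "_co_re.tif"))$meta
    pol_volume(co, cross,
               meta = list(tile_i = m$tile_i, tile_j = m$tile_j,
                           nominal_offset_px = m$nominal_offset_px,
                           lateral_pixel_um = m$lateral_pixel_um,
                           axial_pixel_um = m$axial_pixel_um))
  })
  structure(list(tiles = tiles, layout = layout, cfg = acq$cfg,
                 seed = acq$seed, tile_px = acq$tile_px,
                 depth_um = acq$depth_um),
            class = "psoct_tiles")
}

#' Write polarization maps as 32-bit TIFFs with units in the sidecar
#'
#' @param maps a `polarization_maps` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_polarization_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tiff_stack(maps$reflectivity_db, file.path(dir, "reflectivity.tif"),
                   list(units = "dB"))
  ret <- maps$retardance_deg; ret[!is.finite(ret)] <- 0
  write_tiff_stack(ret, file.path(dir, "retardance.tif"),
                   list(units = "degrees", range = c(0, 90)))
  ori <- maps$orientation_deg
  valid <- is.finite(ori); ori[!valid] <- 0
  write_tiff_stack(ori, file.path(dir, "orientation.tif"),
                   list(units = "degrees", range = c(-90, 90),
                        invalid_flagged = TRUE))
  write_tiff_stack(valid * 1, file.path(dir, "orientation_valid.tif"),
                   list(units = "mask"))
  invisible(dir)
}
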