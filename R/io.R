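#' Write / read a spectral cube as multi-page TIFF with JSON sidecar
#'
#' Wavelength planes become TIFF pages (32-bit float, rescaled to `[0, 1]`);
#' the sidecar (`<path>.json`) records the intensity scale, wavelength grid,
#' pixel size and the reference image, so the round trip is lossless up to
#' float precision.
#'
#' @param cube A [spectral_cube()].
#' @param path TIFF path; the sidecar is written next to it.
#' @return `path` (write) or a [spectral_cube()] (read).
#' @export
write_spectral_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  scale <- max(cube$intensity, 1e-300)
  pages <- lapply(seq_along(cube$lambda_grid),
                  function(j) cube$intensity[, , j] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(type = "spectral_cube", scale = scale,
               lambda_nm = cube$lambda_grid, pixel_size_um = cube$pixel_size,
               reference = cube$reference)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_spectral_cube_tiff
#' @export
read_spectral_cube_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  inten <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
    side$scale
  ref <- side$reference
  if (!is.null(ref)) ref <- matrix(unlist(ref), nrow = dim(inten)[1])
  spectral_cube(inten, lambda_grid = side$lambda_nm, reference = ref,
                pixel_size = side$pixel_size_um)
}

#' Write / read a temporal cube as multi-page TIFF with JSON sidecar
#'
#' Frames become TIFF pages; the sidecar records the intensity scale, frame
#' interval, wavelength and the reference image.
#'
#' @param cube A [temporal_cube()].
#' @param path TIFF path.
#' @return `path` (write) or a [temporal_cube()] (read).
#' @export
write_temporal_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "temporal_cube"))
  scale <- max(cube$intensity, cube$i0, 1e-300)
  pages <- lapply(seq_len(cube$n_frames),
                  function(j) pmax(cube$intensity[, , j], 0) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(type = "temporal_cube", scale = scale,
               frame_interval_s = cube$frame_interval,
               lambda_dyn_nm = cube$lambda_dyn, i0 = cube$i0)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_temporal_cube_tiff
#' @export
read_temporal_cube_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  inten <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
    side$scale
  i0 <- matrix(unlist(side$i0), nrow = dim(inten)[1])
  temporal_cube(inten, i0 = i0, frame_interval = side$frame_interval_s,
                lambda_dyn = side$lambda_dyn_nm)
}

#' Write / read a region scene as TIFF with JSON sidecar
#'
#' Integer labels (including negative micronucleus codes) are offset-scaled
#' into `[0, 1]` for the TIFF; the sidecar restores the integer labels, the
#' pixel size, bleb pairing and the rupture flag.
#'
#' @param scene A `region_scene`.
#' @param path TIFF path.
#' @return `path` (write) or a `region_scene` (read).
#' @export
write_scene_tiff <- function(scene, path) {
  stopifnot(inherits(scene, "region_scene"))
  lab <- scene$label_image
  offset <- min(lab)
  span <- max(diff(range(lab)), 1L)
  tiff::writeTIFF((lab - offset) / span, path, bits.per.sample = 16L)
  side <- list(type = "region_scene", offset = offset, span = span,
               pixel_size_um = scene$pixel_size, ruptured = scene$ruptured,
               pairing = as.list(scene$pairing))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scene_tiff
#' @export
read_scene_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab <- matrix(as.integer(round(img * side$span + side$offset)),
                nrow(img), ncol(img))
  pairing <- unlist(side$pairing)
  structure(list(label_image = lab,
                 pairing = if (is.null(pairing)) integer(0) else pairing,
                 pixel_size = side$pixel_size_um,
                 ruptured = isTRUE(side$ruptured), params = list()),
            class = "region_scene")
}
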