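#' Write a fluorescence image as TIFF with a JSON sidecar
#'
#' The intensity matrix is stored as 32-bit float TIFF scaled into `[0, 1]`;
#' the scale factor, pixel size and interface annotations go into a JSON
#' sidecar next to the TIFF (`<path>.json`), so that
#' [read_image_tiff()] restores the image exactly.
#'
#' @param image A `"fluorescence_image"`.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "fluorescence_image"))
  m <- image$intensity
  scale <- max(m, 1e-12)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  sidecar <- list(
    pixel_size_um = image$pixel_size_um,
    intensity_scale = scale,
    interfaces = image$interfaces
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fluorescence image written by [write_image_tiff()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must exist.
#' @return A `"fluorescence_image"`.
#' @export
read_image_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * side$intensity_scale
  out <- list(
    intensity = m,
    pixel_size_um = side$pixel_size_um,
    interfaces = as.data.frame(side$interfaces)
  )
  class(out) <- "fluorescence_image"
  out
}

#' Write comet tracks to CSV
#'
#' Columns: `track_id`, `cell_id`, `compartment`, `hemisegment`, `t_s`,
#' `x_um`, `y_um`.
#'
#' @param tracks Track data.frame (see [gen_comet_tracks()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Read comet tracks from CSV
#'
#' Accepts either a full track table (as written by [write_tracks_csv()])
#' or a plain one-column angle table (`angle_deg`, degrees), so external
#' angle datasets in that shape can enter the same analyses.
#'
#' @param path CSV path.
#' @return Data.frame of tracks, or of angles if the file only has
#'   `angle_deg`.
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("angle_deg" %in% names(d)) &&
      !all(c("track_id", "t_s", "x_um", "y_um") %in% names(d))) {
    stop("CSV must contain track columns or an angle_deg column", call. = FALSE)
  }
  d
}
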