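## Plain-text / TIFF interchange: track CSVs with JSON metadata sidecars,
## ROI JSON, profile CSVs, and 16-bit TIFF images with calibration sidecars.

#' Write / read tracks as CSV
#'
#' Track tables use the column layout `track_id, frame, x_px` (0-based
#' contiguous frames, integer pixel positions), one file per axon, with an
#' optional `axon_id` column when several axons are pooled.
#'
#' @param tracks data.frame as produced by [simulateTracks()].
#' @param path CSV file path.
#' @return `readTracksCsv` returns the data.frame; `writeTracksCsv` returns
#'   `path` invisibly.
#' @export
writeTracksCsv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTracksCsv
#' @export
readTracksCsv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_px")
  if (!all(need %in% names(tr)))
    stop("track CSV must have columns ", paste(need, collapse = ", "))
  tr
}

#' Write / read axon metadata as JSON
#'
#' Per-axon metadata carries what cannot be inferred from the track file:
#' the kymograph length (for vesicle density), the anterograde sign (the
#' direction toward the distal axon along increasing x) and the calibration.
#'
#' @param metadata data.frame with at least `axon_id, kymo_length_um,
#'   anterograde_sign`.
#' @param path JSON file path.
#' @export
writeAxonMetadata <- function(metadata, path) {
  jsonlite::write_json(metadata, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeAxonMetadata
#' @export
readAxonMetadata <- function(path) {
  md <- jsonlite::fromJSON(path)
  as.data.frame(md)
}

#' Read a polyline ROI from JSON
#'
#' Expected fields: `vertices` (array of `[x, y]` pairs), `width_px`,
#' `anterograde_sign`.
#'
#' @param path JSON file path.
#' @return A [PolylineROI-class].
#' @export
readRoiJson <- function(path) {
  j <- jsonlite::fromJSON(path)
  PolylineROI(matrix(unlist(j$vertices), ncol = 2, byrow = !is.matrix(j$vertices)),
              widthPx = j$width_px %||% 10,
              anterogradeSign = j$anterograde_sign %||% 1)
}

#' @rdname readRoiJson
#' @param roi a [PolylineROI-class].
#' @export
writeRoiJson <- function(roi, path) {
  jsonlite::write_json(
    list(vertices = unname(apply(roi@vertices, 1L, c, simplify = FALSE)),
         width_px = roi@widthPx, anterograde_sign = roi@anterogradeSign),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an image as 16-bit TIFF with a JSON calibration sidecar
#'
#' Intensities are scaled by 1/65535 on write and rescaled on read, so the
#' round trip preserves values up to 16-bit quantization. Calibration
#' (`pixel_size_um`, `frame_interval_s` or `px_nm`) goes to
#' `<path>.json`.
#'
#' @param image numeric matrix (or 3D array for stacks: y, x, time).
#' @param path TIFF file path.
#' @param calibration named list written to the sidecar.
#' @export
writeImageTiff <- function(image, path, calibration = list()) {
  mx <- 65535
  if (length(dim(image)) == 3L) {
    pages <- lapply(seq_len(dim(image)[3L]), function(t)
      pmin(pmax(image[, , t] / mx, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(pmin(pmax(image / mx, 0), 1), path,
                    bits.per.sample = 16)
  }
  if (length(calibration))
    jsonlite::write_json(calibration, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImageTiff
#' @return `readImageTiff` returns a list `image` (matrix or 3D array) and
#'   `calibration` (list, empty when no sidecar exists).
#' @export
readImageTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- if (length(pages) == 1L) pages[[1L]] * 65535 else
    simplify2array(pages) * 65535
  side <- paste0(path, ".json")
  cal <- if (file.exists(side)) jsonlite::fromJSON(side) else list()
  list(image = img, calibration = cal)
}

#' Read an intensity profile from CSV
#'
#' Expected columns: `position_nm, intensity` (or `position_um, intensity`).
#'
#' @param path CSV file path.
#' @param origin label stored in the profile.
#' @return An [IntensityProfile-class].
#' @export
readProfileCsv <- function(path, origin = path) {
  d <- utils::read.csv(path)
  if ("position_nm" %in% names(d)) {
    sp <- diff(d$position_nm[1:2])
    IntensityProfile(d$intensity, spacing = sp, unit = "nm", origin = origin)
  } else if ("position_um" %in% names(d)) {
    sp <- diff(d$position_um[1:2])
    IntensityProfile(d$intensity, spacing = sp, unit = "um", origin = origin)
  } else stop("profile CSV needs position_nm or position_um column")
}
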