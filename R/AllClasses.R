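#' @import methods
NULL

#' Kymograph: a calibrated space-time intensity image
#'
#' A kymograph stores one row per movie frame and one column per position
#' along the axon, together with the spatial and temporal calibration needed
#' to convert pixel displacements into micrometres and seconds.
#'
#' @slot image numeric matrix, time (rows) by arc position (columns).
#' @slot pixelSizeUm spatial calibration in micrometres per pixel.
#' @slot frameIntervalS temporal calibration in seconds per frame.
#' @slot sourceId free-text identifier of the source movie/axon.
#'
#' @seealso [extractKymograph()], [renderKymograph()]
#' @exportClass Kymograph
setClass("Kymograph",
  representation(
    image = "matrix",
    pixelSizeUm = "numeric",
    frameIntervalS = "numeric",
    sourceId = "character"
  )
)

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!is.numeric(object@image)) msg <- c(msg, "image must be numeric")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(object@frameIntervalS) != 1L || object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a Kymograph
#'
#' @param image numeric matrix, time in rows, arc position in columns.
#' @param pixelSizeUm micrometres per pixel (default 0.175).
#' @param frameIntervalS seconds per frame (default 1).
#' @param sourceId identifier string.
#' @return A [Kymograph-class] object.
#' @examples
#' k <- Kymograph(matrix(0, 180, 200))
#' kymoLengthUm(k)
#' @export
Kymograph <- function(image, pixelSizeUm = 0.175, frameIntervalS = 1,
                      sourceId = "") {
  new("Kymograph", image = image, pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS, sourceId = sourceId)
}

#' @describeIn Kymograph physical length covered by the kymograph, in
#'   micrometres (columns times pixel size).
#' @param x,object a `Kymograph`.
#' @export
kymoLengthUm <- function(x) ncol(x@image) * x@pixelSizeUm

#' @describeIn Kymograph the intensity matrix.
#' @export
kymoImage <- function(x) x@image

#' @export
setMethod("show", "Kymograph", function(object) {
  cat("Kymograph:", nrow(object@image), "frames x",
      ncol(object@image), "px (",
      sprintf("%.2f", kymoLengthUm(object)), "um,",
      object@frameIntervalS, "s/frame )\n")
  if (nzchar(object@sourceId)) cat("  source:", object@sourceId, "\n")
})

#' IntensityProfile: a calibrated 1D intensity signal
#'
#' Used both for super-resolution membrane-skeleton profiles (nanometre
#' spacing) and confocal AIS marker profiles (micrometre spacing).
#'
#' @slot values numeric intensity values (arbitrary units).
#' @slot spacing distance between consecutive samples, in `unit`.
#' @slot unit `"nm"` or `"um"`.
#' @slot origin free-text label of the source.
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(values = "numeric", spacing = "numeric",
                 unit = "character", origin = "character")
)

setValidity("IntensityProfile", function(object) {
  msg <- character()
  if (length(object@values) < 2L) msg <- c(msg, "need at least 2 samples")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (!object@unit %in% c("nm", "um"))
    msg <- c(msg, "unit must be 'nm' or 'um'")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityProfile
#'
#' @param values numeric vector of intensities.
#' @param spacing sample spacing, in `unit`.
#' @param unit `"nm"` (super-resolution profiles) or `"um"` (confocal).
#' @param origin label.
#' @return An [IntensityProfile-class] object.
#' @export
IntensityProfile <- function(values, spacing, unit = c("nm", "um"),
                             origin = "") {
  unit <- match.arg(unit)
  new("IntensityProfile", values = as.numeric(values), spacing = spacing,
      unit = unit, origin = origin)
}

#' @describeIn IntensityProfile intensity values.
#' @param x,object an `IntensityProfile`.
#' @export
profileValues <- function(x) x@values

#' @describeIn IntensityProfile sample spacing in nanometres.
#' @export
profileSpacingNm <- function(x)
  if (x@unit == "nm") x@spacing else x@spacing * 1000

#' @describeIn IntensityProfile sample spacing in micrometres.
#' @export
profileSpacingUm <- function(x)
  if (x@unit == "um") x@spacing else x@spacing / 1000

#' @export
setMethod("show", "IntensityProfile", function(object) {
  cat("IntensityProfile:", length(object@values), "samples at",
      object@spacing, object@unit, "/px\n")
  if (nzchar(object@origin)) cat("  origin:", object@origin, "\n")
})

#' AutocorrCurve: normalized spatial autocorrelation of a profile
#'
#' @slot lagsNm lags in nanometres (lag 0 first).
#' @slot values autocorrelation values; 1 at lag 0.
#' @slot sem optional pointwise standard error (for averaged curves;
#'   length 0 otherwise).
#' @slot peakLagNm lag of the first side peak in nanometres, `NA_real_`
#'   when no peak was found.
#' @exportClass AutocorrCurve
setClass("AutocorrCurve",
  representation(lagsNm = "numeric", values = "numeric",
                 sem = "numeric", peakLagNm = "numeric")
)

setValidity("AutocorrCurve", function(object) {
  msg <- character()
  if (length(object@lagsNm) != length(object@values))
    msg <- c(msg, "lagsNm and values must have equal length")
  if (length(object@values) &&
      abs(object@values[1L] - 1) > 1e-8)
    msg <- c(msg, "value at lag 0 must be 1")
  if (length(object@values) && max(abs(object@values)) > 1 + 1e-8)
    msg <- c(msg, "autocorrelation values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "AutocorrCurve", function(object) {
  cat("AutocorrCurve:", length(object@values), "lags up to",
      max(object@lagsNm), "nm; first side peak:",
      if (is.na(object@peakLagNm)) "none" else
        paste0(object@peakLagNm, " nm"), "\n")
})

#' @describeIn AutocorrCurve lag of the first side peak (nm), or `NA`.
#' @param x,object an `AutocorrCurve`.
#' @export
peakLagNm <- function(x) x@peakLagNm

#' PolylineROI: a wide segmented-line region of interest
#'
#' Mirrors the segmented-line selections drawn over individual axons: an
#' ordered list of vertices, a width over which intensity is reduced, and an
#' orientation flag stating whether increasing arc length points away from
#' the soma (anterograde).
#'
#' @slot vertices two-column matrix of (x, y) pixel coordinates, 0-based,
#'   pixel centres at integers.
#' @slot widthPx odd integer width in pixels (10-pixel-wide lines are the
#'   conventional tracing width; see [extractKymograph()]).
#' @slot anterogradeSign +1 if increasing arc length is anterograde
#'   (away from the soma), -1 otherwise.
#' @exportClass PolylineROI
setClass("PolylineROI",
  representation(vertices = "matrix", widthPx = "numeric",
                 anterogradeSign = "numeric")
)

setValidity("PolylineROI", function(object) {
  msg <- character()
  v <- object@vertices
  if (ncol(v) != 2L || nrow(v) < 2L)
    msg <- c(msg, "vertices must be a matrix with >= 2 rows and 2 columns")
  if (nrow(v) >= 2L) {
    d <- sqrt(rowSums((v[-1L, , drop = FALSE] -
                       v[-nrow(v), , drop = FALSE])^2))
    if (any(d == 0)) msg <- c(msg, "consecutive vertices must be distinct")
  }
  if (object@widthPx < 1) msg <- c(msg, "width must be >= 1")
  if (!object@anterogradeSign %in% c(-1, 1))
    msg <- c(msg, "anterogradeSign must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Construct a PolylineROI
#'
#' @param vertices two-column matrix (or data.frame) of x, y pixel
#'   coordinates (0-based, pixel centres at integers).
#' @param widthPx line width in pixels; default 10 matching the
#'   conventional kymograph tracing width.
#' @param anterogradeSign +1 (default) if increasing arc length points away
#'   from the soma, -1 otherwise. Direction cannot be inferred from imagery;
#'   it must be recorded when the axon is traced.
#' @return A [PolylineROI-class] object.
#' @export
PolylineROI <- function(vertices, widthPx = 10, anterogradeSign = 1) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  new("PolylineROI", vertices = vertices, widthPx = widthPx,
      anterogradeSign = anterogradeSign)
}

#' @export
setMethod("show", "PolylineROI", function(object) {
  cat("PolylineROI:", nrow(object@vertices), "vertices, width",
      object@widthPx, "px, arc length",
      sprintf("%.2f", polylineLength(object)), "px\n")
})

#' @describeIn PolylineROI total arc length of the polyline, in pixels.
#' @param x,object a `PolylineROI`.
#' @export
polylineLength <- function(x) {
  v <- x@vertices
  sum(sqrt(rowSums((v[-1L, , drop = FALSE] -
                    v[-nrow(v), , drop = FALSE])^2)))
}
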