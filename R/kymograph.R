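## Kymograph construction: resample a wide polyline ROI at unit arc-length
## spacing and reduce intensity across the line width for every frame.

#' Resample a polyline at uniform arc-length spacing
#'
#' Produces arc-length-uniform sample points along the ROI's polyline,
#' preserving both endpoints, together with the unit normal at each sample
#' (the tangent rotated by 90 degrees; normals are taken from the local
#' segment). The number of samples is `round(arcLength / stepPx) + 1`, so
#' sample spacing equals `stepPx` up to the endpoint-preserving correction.
#'
#' @param roi a [PolylineROI-class].
#' @param stepPx target spacing in pixels (default 1).
#' @return data.frame with columns `x, y` (sample coordinates, 0-based),
#'   `nx, ny` (unit normal) and `s` (arc length at the sample).
#' @examples
#' roi <- PolylineROI(rbind(c(0, 0), c(10, 0)))
#' resamplePolyline(roi)$x
#' @export
resamplePolyline <- function(roi, stepPx = 1) {
  stopifnot(is(roi, "PolylineROI"), stepPx > 0)
  v <- roi@vertices
  seg <- v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
  segLen <- sqrt(rowSums(seg^2))
  L <- sum(segLen)
  if (L <= 0) stop("degenerate polyline: zero total arc length")
  nSamples <- max(2L, round(L / stepPx) + 1L)
  s <- seq(0, L, length.out = nSamples)
  cum <- c(0, cumsum(segLen))
  ## segment index for each sample (last sample belongs to last segment)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > length(segLen)] <- length(segLen)
  frac <- (s - cum[idx]) / segLen[idx]
  x <- v[idx, 1L] + frac * seg[idx, 1L]
  y <- v[idx, 2L] + frac * seg[idx, 2L]
  tx <- seg[idx, 1L] / segLen[idx]
  ty <- seg[idx, 2L] / segLen[idx]
  data.frame(x = x, y = y, nx = -ty, ny = tx, s = s)
}

## Bilinear interpolation on a frame matrix; coordinates are 0-based with
## pixel centres at integers. Out-of-bounds requests error.
.sampleBilinear <- function(frame, x, y) {
  nx <- ncol(frame); ny <- nrow(frame)
  if (any(x < 0 | x > nx - 1 | y < 0 | y > ny - 1))
    stop("ROI samples fall outside the image bounds")
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  v <- frame[i00] * (1 - fx) * (1 - fy) +
    frame[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    frame[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    frame[cbind(y0 + 2, x0 + 2)] * fx * fy
  v
}

.sampleNearest <- function(frame, x, y) {
  nx <- ncol(frame); ny <- nrow(frame)
  xi <- round(x); yi <- round(y)
  if (any(xi < 0 | xi > nx - 1 | yi < 0 | yi > ny - 1))
    stop("ROI samples fall outside the image bounds")
  frame[cbind(yi + 1, xi + 1)]
}

#' Extract a kymograph from a timelapse stack along a wide polyline ROI
#'
#' For every frame and every arc-length sample, intensities at
#' `widthPx` offsets along the local normal are interpolated and reduced to
#' a single value (maximum by default, as appropriate for sparse punctate
#' signal; mean is available). Rows are frames, columns are arc positions.
#'
#' @param stack 3D numeric array `(y, x, time)` or a list of frame matrices.
#' @param roi a [PolylineROI-class]; its width defines the reduction band.
#' @param reducer `"max"` (default) or `"mean"`.
#' @param interpolation `"bilinear"` (default) or `"nearest"` (exact
#'   arithmetic, used by geometry tests).
#' @param pixelSizeUm,frameIntervalS calibration of the stack.
#' @param sourceId identifier stored in the result.
#' @return A [Kymograph-class].
#' @export
extractKymograph <- function(stack, roi, reducer = c("max", "mean"),
                             interpolation = c("bilinear", "nearest"),
                             pixelSizeUm = 0.175, frameIntervalS = 1,
                             sourceId = "") {
  reducer <- match.arg(reducer)
  interpolation <- match.arg(interpolation)
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3L)
  samp <- resamplePolyline(roi, stepPx = 1)
  offs <- seq_len(roi@widthPx) - (roi@widthPx + 1) / 2
  nPos <- nrow(samp)
  nT <- dim(stack)[3L]
  ## offset sample coordinates: one column per width offset
  xs <- sapply(offs, function(o) samp$x + o * samp$nx)
  ys <- sapply(offs, function(o) samp$y + o * samp$ny)
  sampler <- if (interpolation == "bilinear") .sampleBilinear else
    .sampleNearest
  img <- matrix(0, nrow = nT, ncol = nPos)
  red <- if (reducer == "max") function(m) apply(m, 1L, max) else
    function(m) rowMeans(m)
  for (t in seq_len(nT)) {
    fr <- stack[, , t]
    vals <- matrix(sampler(fr, as.vector(xs), as.vector(ys)),
                   nrow = nPos)
    img[t, ] <- red(vals)
  }
  Kymograph(img, pixelSizeUm = pixelSizeUm, frameIntervalS = frameIntervalS,
            sourceId = sourceId)
}
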