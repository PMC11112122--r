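## Two-channel particle-intensity colocalization: detect particles on the
## reference channel, measure integrated density of the same footprints in
## both channels, and quantify their linear relation.

#' Detect particles on channel A and measure both channels
#'
#' Particles are detected on channel A only (thresholded blob detection, see
#' [detectPatches()]); the per-particle integrated density (sum of
#' background-subtracted intensities over the particle footprint) is then
#' measured identically in both channels. Per-channel background is the
#' median intensity outside all detected footprints.
#'
#' @param imageA,imageB co-registered numeric matrices of identical shape;
#'   detection runs on `imageA`.
#' @param paThre,areaThre,smoothingSigmaPx detection parameters, see
#'   [detectPatches()].
#' @return data.frame `particle_id, integdens_a, integdens_b` plus the
#'   footprint centroids `x_px, y_px`.
#' @export
detectParticles2ch <- function(imageA, imageB, paThre = 0.6, areaThre = 0.7,
                               smoothingSigmaPx = 1) {
  if (!identical(dim(imageA), dim(imageB)))
    stop("channel images must have identical shape")
  empty <- data.frame(particle_id = integer(), integdens_a = numeric(),
                      integdens_b = numeric(), x_px = numeric(),
                      y_px = numeric())
  if (max(imageA) == min(imageA)) return(empty)
  sm <- if (smoothingSigmaPx > 0)
    as.matrix(EBImage::gblur(imageA, sigma = smoothingSigmaPx)) else imageA
  bg <- stats::quantile(sm, 0.10, names = FALSE)
  thr <- bg + paThre * (max(sm) - bg)
  mask <- sm > thr
  if (!any(mask)) return(empty)
  lab <- .label8(mask)
  nLab <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = nLab)
  keep <- which(areas >= areaThre * stats::median(areas))
  if (!length(keep)) return(empty)
  outside <- lab == 0L
  bgA <- stats::median(imageA[outside])
  bgB <- stats::median(imageB[outside])
  rows <- lapply(seq_along(keep), function(k) {
    px <- which(lab == keep[k])
    r <- ((px - 1L) %% nrow(imageA)) + 1L
    cc <- ((px - 1L) %/% nrow(imageA)) + 1L
    data.frame(particle_id = k,
               integdens_a = sum(imageA[px] - bgA),
               integdens_b = sum(imageB[px] - bgB),
               x_px = mean(cc - 1L), y_px = mean(r - 1L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear relation between paired particle intensities
#'
#' Ordinary least-squares regression of channel B on channel A, plus the
#' Spearman rank correlation (midrank ties).
#'
#' @param table data.frame with columns `integdens_a` and `integdens_b`
#'   (e.g. from [detectParticles2ch()] or [simulateColocTable()]).
#' @return one-row data.frame `slope, intercept, spearman_r, n`.
#' @examples
#' tab <- simulateColocTable(n = 100, noiseSigma = 0, seed = 1)
#' correlateIntensities(tab)
#' @export
correlateIntensities <- function(table) {
  a <- table$integdens_a
  b <- table$integdens_b
  if (length(a) < 3L) stop("need at least 3 paired particles")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate input: zero variance in one channel")
  fit <- stats::lm(b ~ a)
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             spearman_r = stats::cor(a, b, method = "spearman"),
             n = length(a))
}
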