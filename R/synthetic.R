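## Synthetic generators for every input the pipeline consumes, with ground
## truth, so that classification and structural analyses can be verified
## offline at any scale.

#' Simulate organelle tracks with known per-interval ground truth
#'
#' Generates integer-pixel particle tracks mimicking kymograph tracer output:
#' stationary particles (constant position), and mobile particles alternating
#' directed runs (constant-sign displacement, at least 5 consecutive moving
#' intervals) with pauses (at least 5 consecutive still intervals), plus
#' occasional sub-cutoff oscillation episodes (1-4 frames of +/-1 px jitter
#' inserted between pauses). Continuous positions are simulated and rounded
#' to the pixel grid, because the downstream movement test compares pixel
#' coordinates frame to frame.
#'
#' Run speeds below 1 px/frame are resampled: slower runs cannot be
#' represented on the integer grid without zero-displacement frames, which
#' would contradict the run's ground-truth label. Runs shorter than 5 frames
#' and pauses shorter than 5 frames are likewise resampled, matching the
#' classifier's detection floor. When the final block of a track is cut by
#' the end of the recording and falls below its 5-frame floor, its ground
#' truth is relabelled oscillation, so that on noiseless tracks the
#' classifier's per-interval labels equal the ground truth exactly.
#'
#' @param params a [MotionModelParams-class] object.
#' @param seed integer seed; identical arguments give bit-identical output.
#' @return A list with elements
#'   \describe{
#'     \item{tracks}{data.frame `track_id, frame, x_px` (0-based frames,
#'       integer pixels).}
#'     \item{truth}{list with `states` (per-track character vector of
#'       per-interval labels: `run_antero`, `run_retro`, `pause`,
#'       `oscillation`), `runs` (data.frame of realized per-run direction,
#'       distance in um and mean speed in um/s), and `stationary`
#'       (data.frame `track_id, is_stationary`).}
#'   }
#' @examples
#' sim <- simulateTracks(MotionModelParams(nParticles = 5), seed = 1)
#' head(sim$tracks)
#' @export
simulateTracks <- function(params, seed = 1L) {
  stopifnot(is(params, "MotionModelParams"))
  validObject(params)
  withr::with_seed(seed, .simulateTracksImpl(params))
}

.simulateTracksImpl <- function(params) {
  n <- params@nParticles
  nf <- params@nFrames
  dt <- params@frameIntervalS
  px <- params@pixelSizeUm
  ids <- sprintf("t%04d", seq_len(n))

  trackList <- vector("list", n)
  states <- vector("list", n)
  runsList <- vector("list", n)
  stationary <- logical(n)

  for (i in seq_len(n)) {
    x0 <- round(stats::runif(1, 100, 350))
    if (stats::runif(1) < params@pStationary) {
      ## a stationary particle never moves; the whole span is one pause
      trackList[[i]] <- rep.int(x0, nf)
      states[[i]] <- rep.int("pause", nf - 1L)
      stationary[i] <- TRUE
      next
    }
    blocks <- .drawBlocks(params)
    emit <- .emitTrack(blocks, x0, nf)
    trackList[[i]] <- emit$pos
    states[[i]] <- emit$labels
    stationary[i] <- !any(startsWith(emit$labels, "run"))
    if (!stationary[i]) {
      runsList[[i]] <- .truthRuns(emit$pos, emit$labels, px, dt, ids[i])
    }
  }

  tracks <- data.frame(
    track_id = rep(ids, each = nf),
    frame = rep.int(0:(nf - 1L), n),
    x_px = if (n) as.integer(unlist(trackList)) else integer()
  )
  names(states) <- ids
  runs <- if (length(runsList)) do.call(rbind, runsList) else
    data.frame(track_id = character(), direction = character(),
               n_intervals = integer(), distance_um = numeric(),
               speed_um_s = numeric())
  rownames(runs) <- NULL
  list(tracks = tracks,
       truth = list(states = states, runs = runs,
                    stationary = data.frame(track_id = ids,
                                            is_stationary = stationary)))
}

## Draw an alternating run/pause block sequence (with oscillation episodes
## inserted between pauses) covering at least nFrames-1 intervals.
.drawBlocks <- function(params) {
  nIntervals <- params@nFrames - 1L
  dt <- params@frameIntervalS
  px <- params@pixelSizeUm
  drawRun <- function() {
    dir <- if (stats::runif(1) < params@pRetrogradeRun) "retro" else "antero"
    repeat {
      v <- stats::rlnorm(1, log(params@runSpeedMedianUmS[[dir]]),
                         params@sdlog)
      if (v * dt / px >= 1) break          # representable on pixel grid
    }
    repeat {
      L <- stats::rlnorm(1, log(params@runLengthMedianUm[[dir]]),
                         params@sdlog)
      nfr <- round(L / (v * dt))
      if (nfr >= 5) break                  # detection floor
    }
    list(type = "run", n = nfr,
         sign = if (dir == "retro") -1 else 1, vpx = v * dt / px)
  }
  drawPause <- function() {
    repeat {
      d <- stats::rlnorm(1, log(params@pauseMedianS), params@sdlog)
      nfr <- round(d / dt)
      if (nfr >= 5) break
    }
    list(type = "pause", n = nfr)
  }
  blocks <- list()
  total <- 0L
  nextType <- if (stats::runif(1) < 0.5) "run" else "pause"
  while (total < nIntervals) {
    b <- if (nextType == "run") drawRun() else drawPause()
    blocks[[length(blocks) + 1L]] <- b
    total <- total + b$n
    nextType <- if (nextType == "run") "pause" else "run"
  }
  ## insert oscillation episodes after randomly chosen pauses (each episode
  ## is followed by a fresh pause so jitter never touches a run)
  nOsc <- stats::rpois(1, params@oscillationRate)
  if (nOsc > 0) {
    for (k in seq_len(nOsc)) {
      pauseIdx <- which(vapply(blocks, `[[`, "", "type") == "pause")
      if (!length(pauseIdx)) break
      at <- sample(pauseIdx, 1L)
      osc <- list(type = "osc", n = sample(1:4, 1L),
                  sign = sample(c(-1, 1), 1L))
      blocks <- append(blocks, list(osc, drawPause()), after = at)
    }
  }
  blocks
}

## Emit integer positions and per-interval ground-truth labels, truncating
## to nFrames samples and relabelling a cut final run/pause below its floor.
.emitTrack <- function(blocks, x0, nFrames) {
  pos <- numeric(0)
  labels <- character(0)
  xc <- x0
  for (b in blocks) {
    if (b$type == "run") {
      p <- round(xc + b$sign * b$vpx * seq_len(b$n))
      labels <- c(labels,
                  rep.int(if (b$sign > 0) "run_antero" else "run_retro",
                          b$n))
      xc <- xc + b$sign * b$vpx * b$n
      pos <- c(pos, p)
    } else if (b$type == "pause") {
      pos <- c(pos, rep.int(round(xc), b$n))
      labels <- c(labels, rep.int("pause", b$n))
    } else {
      xi <- round(xc)
      p <- xi + b$sign * (seq_len(b$n) %% 2L)
      pos <- c(pos, p)
      labels <- c(labels, rep.int("oscillation", b$n))
      xc <- xc + b$sign * (b$n %% 2L)
    }
    if (length(pos) >= nFrames - 1L) break
  }
  pos <- c(x0, pos)[seq_len(nFrames)]
  labels <- labels[seq_len(nFrames - 1L)]
  ## relabel a truncated trailing block that fell below its 5-frame floor
  r <- rle(labels)
  lastLen <- r$lengths[length(r$lengths)]
  lastVal <- r$values[length(r$values)]
  if (lastLen < 5 && lastVal %in% c("run_antero", "run_retro", "pause")) {
    labels[(length(labels) - lastLen + 1L):length(labels)] <- "oscillation"
  }
  list(pos = pos, labels = labels)
}

## Realized per-run distances/speeds from emitted positions and labels.
.truthRuns <- function(pos, labels, px, dt, id) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- startsWith(r$values, "run")
  if (!any(keep)) return(NULL)
  out <- lapply(which(keep), function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    dist <- abs(pos[i1 + 1L] - pos[i0]) * px
    data.frame(track_id = id,
               direction = if (r$values[j] == "run_antero")
                 "anterograde" else "retrograde",
               n_intervals = r$lengths[j],
               distance_um = dist,
               speed_um_s = dist / (r$lengths[j] * dt))
  })
  do.call(rbind, out)
}

#' Simulate a cohort of axons with per-axon tracks and metadata
#'
#' Convenience wrapper around [simulateTracks()] producing one simulated
#' axon per call with shared model parameters, the per-axon metadata
#' required by [classifyCohort()], and pooled ground truth.
#'
#' @param nAxons number of axons.
#' @param tracksPerAxon particles per axon.
#' @param params a [MotionModelParams-class]; its `nParticles` is overridden
#'   by `tracksPerAxon`.
#' @param kymoLengthUm physical length of each (virtual) kymograph, um.
#' @param seed integer seed.
#' @return list with `tracks` (data.frame with `axon_id`), `metadata`
#'   (data.frame `axon_id, kymo_length_um, anterograde_sign`), `truth`
#'   (list of per-axon truth objects).
#' @export
simulateCohort <- function(nAxons, tracksPerAxon,
                           params = MotionModelParams(),
                           kymoLengthUm = 80, seed = 1L) {
  params@nParticles <- tracksPerAxon
  axonIds <- sprintf("axon%03d", seq_len(nAxons))
  axonSeeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, nAxons))
  sims <- lapply(seq_len(nAxons), function(a)
    simulateTracks(params, seed = axonSeeds[a]))
  tracks <- do.call(rbind, lapply(seq_len(nAxons), function(a) {
    tr <- sims[[a]]$tracks
    tr$axon_id <- axonIds[a]
    tr$track_id <- paste0(axonIds[a], "_", tr$track_id)
    tr
  }))
  rownames(tracks) <- NULL
  metadata <- data.frame(axon_id = axonIds,
                         kymo_length_um = kymoLengthUm,
                         anterograde_sign = 1)
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- axonIds
  list(tracks = tracks, metadata = metadata, truth = truth)
}

#' Render tracks into a synthetic kymograph image
#'
#' Each particle contributes a Gaussian intensity bump centred at its
#' position in every frame, on a constant background, with optional additive
#' Gaussian noise.
#'
#' @param tracks data.frame `track_id, frame, x_px` as from
#'   [simulateTracks()]; all tracks must share the same frame range.
#' @param spacePx number of spatial pixels (columns).
#' @param psfSigmaPx Gaussian bump sigma in pixels.
#' @param amplitude peak intensity per particle (AU).
#' @param background constant background level (AU).
#' @param noiseSigma additive Gaussian noise sigma (AU); 0 for noiseless.
#' @param pixelSizeUm,frameIntervalS calibration stored in the result.
#' @param seed integer seed for the noise.
#' @return A [Kymograph-class] (rows = frames, columns = space).
#' @export
renderKymograph <- function(tracks, spacePx, psfSigmaPx = 2,
                            amplitude = 1000, background = 100,
                            noiseSigma = 0, pixelSizeUm = 0.175,
                            frameIntervalS = 1, seed = 1L) {
  stopifnot(noiseSigma >= 0, spacePx >= 1)
  if (nrow(tracks) && (min(tracks$x_px) < 0 || max(tracks$x_px) > spacePx - 1))
    stop("track coordinates exceed the spatial extent [0, spacePx)")
  frames <- sort(unique(tracks$frame))
  nFrames <- if (length(frames)) max(frames) + 1L else 0L
  img <- matrix(background, nrow = nFrames, ncol = spacePx)
  xgrid <- 0:(spacePx - 1L)
  for (k in seq_len(nrow(tracks))) {
    t <- tracks$frame[k] + 1L
    img[t, ] <- img[t, ] + amplitude *
      exp(-((xgrid - tracks$x_px[k])^2) / (2 * psfSigmaPx^2))
  }
  if (noiseSigma > 0) {
    img <- img + withr::with_seed(seed,
      matrix(stats::rnorm(length(img), 0, noiseSigma), nrow = nFrames))
  }
  Kymograph(img, pixelSizeUm = pixelSizeUm, frameIntervalS = frameIntervalS,
            sourceId = "synthetic")
}

#' Simulate a membrane periodic skeleton intensity profile
#'
#' A sum of Gaussian peaks on a regular lattice (the actin-spectrin
#' membrane-associated periodic skeleton has a ~190 nm longitudinal period)
#' plus seeded Gaussian noise, sampled on a super-resolution pixel grid.
#'
#' @param spacingNm lattice period, nm (default 190).
#' @param pxNm pixel size, nm (default 30, typical STED sampling).
#' @param lengthUm profile length, um; must cover at least 10 periods.
#' @param peakSigmaNm Gaussian peak sigma, nm (default 50).
#' @param noiseFrac noise sigma as a fraction of the peak amplitude.
#' @param seed integer seed.
#' @return An [IntensityProfile-class] with nm spacing.
#' @export
simulateMpsProfile <- function(spacingNm = 190, pxNm = 30, lengthUm = 10,
                               peakSigmaNm = 50, noiseFrac = 0.1,
                               seed = 1L) {
  if (spacingNm <= 2 * pxNm)
    stop("undersampled lattice: spacingNm must exceed 2 * pxNm")
  lengthNm <- lengthUm * 1000
  if (lengthNm < 10 * spacingNm)
    stop("profile must cover at least 10 lattice periods")
  n <- round(lengthNm / pxNm)
  x <- (0:(n - 1L)) * pxNm
  centers <- seq(spacingNm / 2, lengthNm, by = spacingNm)
  v <- rowSums(vapply(centers, function(c0)
    exp(-((x - c0)^2) / (2 * peakSigmaNm^2)), numeric(n)))
  if (noiseFrac > 0) {
    v <- v + withr::with_seed(seed, stats::rnorm(n, 0, noiseFrac))
  }
  IntensityProfile(v, spacing = pxNm, unit = "nm", origin = "synthetic MPS")
}

#' Simulate a super-resolution AIS image with F-actin-like patches
#'
#' Places `nPatches` Gaussian blobs at random positions (kept clear of the
#' image border and of each other) on a dark background, with optional
#' additive Gaussian noise, and returns the ground-truth centroids.
#'
#' @param nPatches number of blobs.
#' @param patchSigmaPx blob sigma in pixels.
#' @param amplitude peak intensity (AU).
#' @param imageShape `c(nrow, ncol)` in pixels.
#' @param noiseSigma additive Gaussian noise sigma (AU).
#' @param minSepPx minimum centre-to-centre separation; default `6 *
#'   patchSigmaPx` keeps blobs resolvable.
#' @param seed integer seed.
#' @return list with `image` (matrix) and `truth` (data.frame
#'   `patch_id, x_px, y_px` of true centroids, 0-based pixel coordinates).
#' @export
simulateAisImage <- function(nPatches, patchSigmaPx = 3, amplitude = 1000,
                             imageShape = c(64, 256), noiseSigma = 0,
                             minSepPx = 6 * patchSigmaPx, seed = 1L) {
  stopifnot(nPatches >= 0, noiseSigma >= 0)
  margin <- 4 * patchSigmaPx
  if (2 * margin >= min(imageShape))
    stop("patches do not fit in the image without touching borders")
  withr::with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < nPatches) {
      cand <- c(stats::runif(1, margin, imageShape[2] - 1 - margin),
                stats::runif(1, margin, imageShape[1] - 1 - margin))
      ok <- !nrow(centers) ||
        all(sqrt((centers[, 1] - cand[1])^2 +
                 (centers[, 2] - cand[2])^2) >= minSepPx)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 10000L)
        stop("cannot place ", nPatches,
             " non-overlapping patches in this image (packing limit)")
    }
    img <- matrix(0, imageShape[1], imageShape[2])
    xg <- 0:(imageShape[2] - 1L)
    yg <- 0:(imageShape[1] - 1L)
    for (k in seq_len(nPatches)) {
      img <- img + amplitude *
        outer(exp(-((yg - centers[k, 2])^2) / (2 * patchSigmaPx^2)),
              exp(-((xg - centers[k, 1])^2) / (2 * patchSigmaPx^2)))
    }
    if (noiseSigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noiseSigma),
                          nrow = imageShape[1])
    truth <- data.frame(
      patch_id = seq_len(nPatches),
      x_px = if (nPatches) centers[, 1] else numeric(),
      y_px = if (nPatches) centers[, 2] else numeric())
    list(image = img, truth = truth)
  })
}

#' Simulate an AIS marker intensity profile
#'
#' A smoothed plateau with error-function edges, emulating the intensity of
#' an AIS marker (AnkG or TRIM46) along the proximal axon; the plateau
#' extent is the ground-truth AIS length.
#'
#' @param trueLengthUm plateau extent, um (default 27.5, a typical
#'   wild-type AnkG-based AIS length).
#' @param pxUm sample spacing, um (default 0.09, confocal sampling).
#' @param edgeSigmaUm edge smoothing sigma, um; must satisfy
#'   `trueLengthUm > 4 * edgeSigmaUm`.
#' @param noiseFrac noise sigma as fraction of plateau amplitude.
#' @param marginUm flat margin added on each side (default 10).
#' @param seed integer seed.
#' @return An [IntensityProfile-class] with um spacing.
#' @export
simulateAisMarkerProfile <- function(trueLengthUm = 27.5, pxUm = 0.09,
                                     edgeSigmaUm = 1, noiseFrac = 0,
                                     marginUm = 10, seed = 1L) {
  if (trueLengthUm <= 4 * edgeSigmaUm)
    stop("trueLengthUm must exceed 4 * edgeSigmaUm")
  total <- trueLengthUm + 2 * marginUm
  n <- round(total / pxUm)
  x <- (0:(n - 1L)) * pxUm
  a <- marginUm
  b <- marginUm + trueLengthUm
  v <- if (edgeSigmaUm > 0)
    stats::pnorm((x - a) / edgeSigmaUm) - stats::pnorm((x - b) / edgeSigmaUm)
  else as.numeric(x >= a & x < b)
  if (noiseFrac > 0)
    v <- v + withr::with_seed(seed, stats::rnorm(n, 0, noiseFrac))
  IntensityProfile(v, spacing = pxUm, unit = "um",
                   origin = "synthetic AIS marker")
}

#' Simulate a paired two-channel particle-intensity table
#'
#' Paired integrated densities with a linear coupling
#' `b = slope * a + intercept + noise`, emulating the relation between a
#' detection channel and a second readout channel measured over the same
#' particle footprints. Defaults reproduce the fitted endolysosome
#' relation `y = 1578 x + 4156` over 815 particles.
#'
#' @param n number of particles (default 815).
#' @param slope,intercept linear coupling (defaults 1578 and 4156).
#' @param noiseSigma additive Gaussian noise sigma on channel B.
#' @param xRange range of channel-A intensities, drawn uniformly.
#' @param seed integer seed.
#' @return data.frame `particle_id, integdens_a, integdens_b`.
#' @export
simulateColocTable <- function(n = 815, slope = 1578, intercept = 4156,
                               noiseSigma = 0, xRange = c(5, 105),
                               seed = 1L) {
  stopifnot(n >= 3, noiseSigma >= 0)
  withr::with_seed(seed, {
    a <- stats::runif(n, xRange[1], xRange[2])
    b <- slope * a + intercept +
      if (noiseSigma > 0) stats::rnorm(n, 0, noiseSigma) else 0
    data.frame(particle_id = seq_len(n), integdens_a = a, integdens_b = b)
  })
}
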