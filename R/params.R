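#' MotionModelParams: generative parameters for the track simulator
#'
#' Parameters of the stochastic motion model used by [simulateTracks()].
#' Mobile particles alternate directed runs and pauses, with occasional
#' sub-cutoff oscillation episodes; stationary particles never move. Run
#' lengths, run speeds and pause durations are drawn from log-normal
#' distributions parameterized by their median (the value the downstream
#' classifier should recover) and a common log-scale spread.
#'
#' The defaults encode the wild-type trafficking statistics of axonal
#' endolysosomes in cultured hippocampal neurons: 56% of tracks stationary,
#' median pause 16.4 s, median anterograde speed 0.43 um/s and run distance
#' 5.88 um, median retrograde speed 0.48 um/s and run distance 8.71 um,
#' imaged at 0.175 um/px every 1 s for 180 frames.
#'
#' @slot nParticles number of particles (tracks) to simulate.
#' @slot nFrames frames per track (default 180).
#' @slot frameIntervalS seconds per frame (default 1).
#' @slot pixelSizeUm micrometres per pixel (default 0.175).
#' @slot pStationary probability a particle has no runs at all.
#' @slot runLengthMedianUm named numeric `c(antero=, retro=)`: median run
#'   distance per direction, micrometres.
#' @slot runSpeedMedianUmS named numeric `c(antero=, retro=)`: median run
#'   speed per direction, micrometres per second.
#' @slot pauseMedianS median pause duration, seconds (support kept >= the
#'   5-frame detection floor).
#' @slot sdlog log-scale standard deviation shared by the three log-normal
#'   families (default 0.3, moderate biological spread).
#' @slot pRetrogradeRun probability that a run is retrograde.
#' @slot oscillationRate expected number of 1-4 frame jitter episodes per
#'   mobile track.
#' @exportClass MotionModelParams
setClass("MotionModelParams",
  representation(
    nParticles = "numeric", nFrames = "numeric",
    frameIntervalS = "numeric", pixelSizeUm = "numeric",
    pStationary = "numeric",
    runLengthMedianUm = "numeric", runSpeedMedianUmS = "numeric",
    pauseMedianS = "numeric", sdlog = "numeric",
    pRetrogradeRun = "numeric", oscillationRate = "numeric"
  )
)

setValidity("MotionModelParams", function(object) {
  msg <- character()
  chkProb <- function(p, nm) {
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
      sprintf("%s must be a probability in [0, 1]", nm) else character()
  }
  msg <- c(msg, chkProb(object@pStationary, "pStationary"),
           chkProb(object@pRetrogradeRun, "pRetrogradeRun"))
  if (object@nParticles < 0) msg <- c(msg, "nParticles must be >= 0")
  if (object@nFrames < 20) msg <- c(msg, "nFrames must be >= 20")
  for (nm in c("runLengthMedianUm", "runSpeedMedianUmS")) {
    v <- slot(object, nm)
    if (length(v) != 2L || !all(c("antero", "retro") %in% names(v)) ||
        any(v <= 0))
      msg <- c(msg, sprintf("%s must be positive and named antero/retro", nm))
  }
  if (object@pauseMedianS <= 0) msg <- c(msg, "pauseMedianS must be > 0")
  if (object@pauseMedianS < 5 * object@frameIntervalS)
    msg <- c(msg, "pauseMedianS must be >= the 5-frame pause floor")
  if (object@sdlog < 0) msg <- c(msg, "sdlog must be >= 0")
  if (object@oscillationRate < 0) msg <- c(msg, "oscillationRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct MotionModelParams (wild-type preset by default)
#'
#' @param nParticles number of tracks.
#' @param nFrames frames per track.
#' @param frameIntervalS seconds per frame.
#' @param pixelSizeUm micrometres per pixel.
#' @param pStationary probability a track is stationary.
#' @param runLengthMedianUm median run distance, `c(antero=, retro=)`, um.
#' @param runSpeedMedianUmS median run speed, `c(antero=, retro=)`, um/s.
#' @param pauseMedianS median pause duration, s.
#' @param sdlog log-normal spread shared by the length/speed/pause families.
#' @param pRetrogradeRun probability a run is retrograde.
#' @param oscillationRate expected jitter episodes per mobile track.
#' @return A [MotionModelParams-class] object.
#' @examples
#' p <- MotionModelParams(nParticles = 10)
#' p
#' @export
MotionModelParams <- function(nParticles = 20, nFrames = 180,
                              frameIntervalS = 1, pixelSizeUm = 0.175,
                              pStationary = 0.56,
                              runLengthMedianUm = c(antero = 5.88,
                                                    retro = 8.71),
                              runSpeedMedianUmS = c(antero = 0.43,
                                                    retro = 0.48),
                              pauseMedianS = 16.4, sdlog = 0.3,
                              pRetrogradeRun = 0.5, oscillationRate = 1) {
  new("MotionModelParams", nParticles = nParticles, nFrames = nFrames,
      frameIntervalS = frameIntervalS, pixelSizeUm = pixelSizeUm,
      pStationary = pStationary, runLengthMedianUm = runLengthMedianUm,
      runSpeedMedianUmS = runSpeedMedianUmS, pauseMedianS = pauseMedianS,
      sdlog = sdlog, pRetrogradeRun = pRetrogradeRun,
      oscillationRate = oscillationRate)
}

#' @export
setMethod("show", "MotionModelParams", function(object) {
  cat("MotionModelParams:", object@nParticles, "particles x",
      object@nFrames, "frames @", object@frameIntervalS, "s,",
      object@pixelSizeUm, "um/px\n")
  cat(sprintf("  P(stationary)=%.2f  P(retro run)=%.2f  pause median %.1f s\n",
              object@pStationary, object@pRetrogradeRun, object@pauseMedianS))
  cat(sprintf("  run median: antero %.2f um @ %.2f um/s; retro %.2f um @ %.2f um/s\n",
              object@runLengthMedianUm[["antero"]],
              object@runSpeedMedianUmS[["antero"]],
              object@runLengthMedianUm[["retro"]],
              object@runSpeedMedianUmS[["retro"]]))
})

#' TrackMotionConfig: thresholds for the run/pause/oscillation classifier
#'
#' Encodes the movement test and cutoffs of the trafficking analysis: a
#' particle is "moving" between two frames when its x coordinate changes;
#' a run is continuous single-direction movement for at least
#' `minRunFrames` frame intervals; a pause is continuous non-movement for
#' at least `minPauseFrames` intervals (counted only in mobile tracks);
#' everything shorter is oscillation. Net displacement of a mobile track is
#' classified anterograde/retrograde only when at least
#' `netDispThresholdPx` pixels (0.875 um at defaults).
#'
#' @slot pixelSizeUm micrometres per pixel (default 0.175).
#' @slot frameIntervalS seconds per frame (default 1).
#' @slot minRunFrames minimum frame intervals for a run (default 5).
#' @slot minPauseFrames minimum frame intervals for a pause (default 5).
#' @slot netDispThresholdPx net-displacement threshold in pixels (default 5).
#' @slot movementEpsPx |dx| must exceed this for "movement" (default 0.5:
#'   reproduces the changed/stayed-the-same test on integer-pixel tracks
#'   while tolerating sub-pixel float output).
#' @slot minTrackFrames minimum samples per track; shorter tracks are
#'   rejected (default 20).
#' @slot anterogradeSign +1 if increasing x is anterograde, else -1.
#' @exportClass TrackMotionConfig
setClass("TrackMotionConfig",
  representation(
    pixelSizeUm = "numeric", frameIntervalS = "numeric",
    minRunFrames = "numeric", minPauseFrames = "numeric",
    netDispThresholdPx = "numeric", movementEpsPx = "numeric",
    minTrackFrames = "numeric", anterogradeSign = "numeric"
  )
)

setValidity("TrackMotionConfig", function(object) {
  msg <- character()
  if (object@minRunFrames < 1) msg <- c(msg, "minRunFrames must be >= 1")
  if (object@minPauseFrames < 1) msg <- c(msg, "minPauseFrames must be >= 1")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (object@movementEpsPx < 0) msg <- c(msg, "movementEpsPx must be >= 0")
  if (object@minTrackFrames < 2) msg <- c(msg, "minTrackFrames must be >= 2")
  if (!object@anterogradeSign %in% c(-1, 1))
    msg <- c(msg, "anterogradeSign must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Construct a TrackMotionConfig
#'
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalS seconds per frame.
#' @param minRunFrames minimum frame intervals for a run.
#' @param minPauseFrames minimum frame intervals for a pause.
#' @param netDispThresholdPx net-displacement threshold in pixels.
#' @param movementEpsPx movement test epsilon in pixels.
#' @param minTrackFrames minimum samples per accepted track.
#' @param anterogradeSign +1 or -1.
#' @return A [TrackMotionConfig-class] object.
#' @examples
#' cfg <- TrackMotionConfig()
#' cfg@netDispThresholdPx * cfg@pixelSizeUm   # 0.875 um
#' @export
TrackMotionConfig <- function(pixelSizeUm = 0.175, frameIntervalS = 1,
                              minRunFrames = 5, minPauseFrames = 5,
                              netDispThresholdPx = 5, movementEpsPx = 0.5,
                              minTrackFrames = 20, anterogradeSign = 1) {
  new("TrackMotionConfig", pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS, minRunFrames = minRunFrames,
      minPauseFrames = minPauseFrames,
      netDispThresholdPx = netDispThresholdPx,
      movementEpsPx = movementEpsPx, minTrackFrames = minTrackFrames,
      anterogradeSign = anterogradeSign)
}

#' @export
setMethod("show", "TrackMotionConfig", function(object) {
  cat("TrackMotionConfig:",
      sprintf("run >= %d, pause >= %d intervals; net threshold %g px (%.3f um)",
              as.integer(object@minRunFrames),
              as.integer(object@minPauseFrames),
              object@netDispThresholdPx,
              object@netDispThresholdPx * object@pixelSizeUm), "\n")
  cat(sprintf("  %.3f um/px, %g s/frame, min track %d frames, antero sign %+d\n",
              object@pixelSizeUm, object@frameIntervalS,
              as.integer(object@minTrackFrames),
              as.integer(object@anterogradeSign)))
})
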