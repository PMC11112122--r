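## Run/pause/oscillation classification of kymograph particle tracks and
## per-axon aggregation of trafficking statistics.

#' Movement flags for one track
#'
#' Applies the frame-to-frame movement test: an interval counts as movement
#' when the x coordinate changes by more than `movementEpsPx` (0.5 px by
#' default, which on integer-pixel tracks is exactly the changed /
#' stayed-the-same test).
#'
#' @param track data.frame with columns `frame` (strictly increasing,
#'   contiguous, 0-based) and `x_px`.
#' @param cfg a [TrackMotionConfig-class].
#' @return list with `moving` (logical, length `nrow(track) - 1`) and
#'   `sign` (integer -1/0/+1 displacement signs per interval).
#' @export
binarizeMotion <- function(track, cfg = TrackMotionConfig()) {
  stopifnot(nrow(track) >= 2L)
  f <- track$frame
  if (any(diff(f) != 1L))
    stop("track frames must be contiguous (missing frames are not interpolated)")
  dx <- diff(track$x_px)
  list(moving = abs(dx) > cfg@movementEpsPx, sign = sign(dx))
}

#' Segment movement flags into runs, pauses and oscillation
#'
#' Maximal constant-motion-state intervals are formed first; moving
#' intervals are additionally split at displacement-sign reversals so that
#' every run has a single direction. Moving (sub)intervals of at least
#' `minRunFrames` become runs; non-moving intervals of at least
#' `minPauseFrames` become pauses; everything below those cutoffs is
#' oscillation. Segments tile the track exactly.
#'
#' @param flags output of [binarizeMotion()].
#' @param cfg a [TrackMotionConfig-class].
#' @return data.frame with one row per segment: `state` (run / pause /
#'   oscillation), `direction` (anterograde / retrograde / none),
#'   `start_frame`, `end_frame` (0-based; the segment spans the intervals
#'   `start_frame .. end_frame`), `n_intervals`, `duration_s`.
#' @export
segmentStates <- function(flags, cfg = TrackMotionConfig()) {
  moving <- flags$moving
  sgn <- flags$sign
  n <- length(moving)
  ## group id: changes when the moving flag changes, or (within a moving
  ## stretch) when the displacement sign reverses
  brk <- logical(n)
  if (n > 1L) {
    chgMove <- moving[-1L] != moving[-n]
    chgSign <- moving[-1L] & moving[-n] & (sgn[-1L] != sgn[-n])
    brk[-1L] <- chgMove | chgSign
  }
  grp <- cumsum(c(TRUE, brk[-1L]))
  starts <- which(c(TRUE, brk[-1L]))
  lens <- tabulate(grp)
  ends <- starts + lens - 1L

  state <- character(length(starts))
  direction <- rep("none", length(starts))
  for (j in seq_along(starts)) {
    if (moving[starts[j]]) {
      if (lens[j] >= cfg@minRunFrames) {
        state[j] <- "run"
        d <- sgn[starts[j]] * cfg@anterogradeSign
        direction[j] <- if (d > 0) "anterograde" else "retrograde"
      } else state[j] <- "oscillation"
    } else {
      state[j] <- if (lens[j] >= cfg@minPauseFrames) "pause" else
        "oscillation"
    }
  }
  data.frame(state = state, direction = direction,
             start_frame = starts - 1L, end_frame = ends - 1L,
             n_intervals = lens,
             duration_s = lens * cfg@frameIntervalS)
}

#' Classify one track into segments and per-track trafficking metrics
#'
#' Runs the movement test and segmentation, then computes per-run distance
#' (sum of per-frame |dx| over the run, converted to micrometres) and mean
#' speed, pause durations (reported only for mobile tracks, i.e. tracks
#' containing at least one run), and the net displacement. A mobile track's
#' net direction is anterograde or retrograde only when the end-minus-start
#' displacement reaches `netDispThresholdPx` pixels (0.875 um at defaults);
#' otherwise, and for stationary tracks, it is `"none"`.
#'
#' @param track data.frame `frame, x_px` (plus optional `track_id`).
#' @param cfg a [TrackMotionConfig-class].
#' @return list of class `trackMetrics`: `track_id`, `is_stationary`,
#'   `segments` (from [segmentStates()], with `distance_um` and
#'   `mean_speed_um_s` filled in for runs), `n_runs_antero`, `n_runs_retro`,
#'   `mean_run_distance_um` and `mean_speed_um_s` (named `c(antero=,
#'   retro=)`, `NA` where the track has no run in that direction),
#'   `pause_durations_s`, `net_displacement_um` (signed, anterograde
#'   positive), `net_direction`.
#' @examples
#' tr <- data.frame(frame = 0:20, x_px = 0:20)
#' m <- classifyTrack(tr)
#' m$segments
#' @export
classifyTrack <- function(track, cfg = TrackMotionConfig()) {
  if (nrow(track) < cfg@minTrackFrames)
    stop("track shorter than minTrackFrames (", cfg@minTrackFrames,
         " samples)")
  id <- if (!is.null(track$track_id)) as.character(track$track_id[1L]) else ""
  flags <- binarizeMotion(track, cfg)
  seg <- segmentStates(flags, cfg)

  dx <- diff(track$x_px)
  seg$distance_um <- NA_real_
  seg$mean_speed_um_s <- NA_real_
  isRun <- seg$state == "run"
  for (j in which(isRun)) {
    iv <- (seg$start_frame[j] + 1L):(seg$end_frame[j] + 1L)
    seg$distance_um[j] <- sum(abs(dx[iv])) * cfg@pixelSizeUm
    seg$mean_speed_um_s[j] <- seg$distance_um[j] / seg$duration_s[j]
  }

  isStationary <- !any(isRun)
  dirOf <- function(d) isRun & seg$direction == d
  meanOrNA <- function(v) if (length(v)) mean(v) else NA_real_
  runDist <- c(antero = meanOrNA(seg$distance_um[dirOf("anterograde")]),
               retro = meanOrNA(seg$distance_um[dirOf("retrograde")]))
  runSpeed <- c(antero = meanOrNA(seg$mean_speed_um_s[dirOf("anterograde")]),
                retro = meanOrNA(seg$mean_speed_um_s[dirOf("retrograde")]))
  pauses <- if (isStationary) numeric(0) else
    seg$duration_s[seg$state == "pause"]

  netPx <- track$x_px[nrow(track)] - track$x_px[1L]
  netUm <- netPx * cfg@pixelSizeUm * cfg@anterogradeSign
  netDir <- "none"
  if (!isStationary && abs(netPx) >= cfg@netDispThresholdPx)
    netDir <- if (netUm > 0) "anterograde" else "retrograde"

  structure(list(
    track_id = id,
    is_stationary = isStationary,
    segments = seg,
    n_runs_antero = sum(dirOf("anterograde")),
    n_runs_retro = sum(dirOf("retrograde")),
    mean_run_distance_um = runDist,
    mean_speed_um_s = runSpeed,
    pause_durations_s = pauses,
    net_displacement_um = netUm,
    net_direction = netDir
  ), class = "trackMetrics")
}

#' @export
print.trackMetrics <- function(x, ...) {
  cat("trackMetrics", x$track_id,
      if (x$is_stationary) "(stationary)" else "(mobile)", "\n")
  cat("  runs: ", x$n_runs_antero, "antero,", x$n_runs_retro, "retro;",
      length(x$pause_durations_s), "pauses; net",
      sprintf("%.2f um (%s)", x$net_displacement_um, x$net_direction), "\n")
  invisible(x)
}

#' Aggregate per-track metrics into a per-axon summary
#'
#' Per-axon values are means over tracks (the per-track means being the
#' underlying unit), matching per-axon averaging with group n = axons.
#' Directional speed/distance means are taken over tracks that have at least
#' one run in that direction. Vesicle density uses all accepted tracks.
#'
#' @param metricsList list of `trackMetrics` from [classifyTrack()].
#' @param kymoLengthUm physical length of the kymograph, um.
#' @param cfg a [TrackMotionConfig-class].
#' @param axonId identifier for the output row.
#' @return one-row data.frame: `axon_id, n_tracks, vesicles_per_10um,
#'   pct_stationary, mean_pause_s, mean_speed_antero_um_s,
#'   mean_speed_retro_um_s, mean_run_dist_antero_um, mean_run_dist_retro_um,
#'   mean_net_displacement_um, n_net_antero, n_net_retro, n_net_none,
#'   pct_net_antero, pct_net_retro, pct_net_none` (percentages of mobile
#'   tracks per net-direction class).
#' @export
summarizeAxon <- function(metricsList, kymoLengthUm,
                          cfg = TrackMotionConfig(), axonId = "") {
  stopifnot(kymoLengthUm > 0)
  n <- length(metricsList)
  if (n == 0L) {
    return(data.frame(axon_id = axonId, n_tracks = 0L,
                      vesicles_per_10um = 0,
                      pct_stationary = NA_real_, mean_pause_s = NA_real_,
                      mean_speed_antero_um_s = NA_real_,
                      mean_speed_retro_um_s = NA_real_,
                      mean_run_dist_antero_um = NA_real_,
                      mean_run_dist_retro_um = NA_real_,
                      mean_net_displacement_um = NA_real_,
                      n_net_antero = 0L, n_net_retro = 0L, n_net_none = 0L,
                      pct_net_antero = NA_real_, pct_net_retro = NA_real_,
                      pct_net_none = NA_real_))
  }
  g <- function(f) vapply(metricsList, f, numeric(1))
  stat <- vapply(metricsList, `[[`, logical(1), "is_stationary")
  meanNA <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  pauseMeans <- g(function(m)
    if (length(m$pause_durations_s)) mean(m$pause_durations_s) else NA_real_)
  netDir <- vapply(metricsList, `[[`, character(1), "net_direction")
  mobile <- !stat
  nMobile <- sum(mobile)
  pctNet <- function(d) if (nMobile) 100 * sum(netDir[mobile] == d) / nMobile
    else NA_real_
  data.frame(
    axon_id = axonId,
    n_tracks = n,
    vesicles_per_10um = n / kymoLengthUm * 10,
    pct_stationary = 100 * mean(stat),
    mean_pause_s = meanNA(pauseMeans),
    mean_speed_antero_um_s = meanNA(g(function(m)
      m$mean_speed_um_s[["antero"]])),
    mean_speed_retro_um_s = meanNA(g(function(m)
      m$mean_speed_um_s[["retro"]])),
    mean_run_dist_antero_um = meanNA(g(function(m)
      m$mean_run_distance_um[["antero"]])),
    mean_run_dist_retro_um = meanNA(g(function(m)
      m$mean_run_distance_um[["retro"]])),
    mean_net_displacement_um = meanNA(g(function(m)
      if (m$is_stationary) NA_real_ else m$net_displacement_um)),
    n_net_antero = sum(netDir == "anterograde"),
    n_net_retro = sum(netDir == "retrograde"),
    n_net_none = sum(netDir == "none" & mobile),
    pct_net_antero = pctNet("anterograde"),
    pct_net_retro = pctNet("retrograde"),
    pct_net_none = pctNet("none")
  )
}

#' Classify a cohort of axons
#'
#' Applies [classifyTrack()] to every track of every axon and
#' [summarizeAxon()] per axon. Tracks shorter than `minTrackFrames` are
#' rejected and logged, not classified. The output is ordered by `axon_id`,
#' so it is invariant to the input row order.
#'
#' @param tracks data.frame `axon_id, track_id, frame, x_px` (all axons
#'   pooled), e.g. from [simulateCohort()] or [readTracksCsv()].
#' @param metadata data.frame `axon_id, kymo_length_um, anterograde_sign`.
#' @param cfg a [TrackMotionConfig-class]; its `anterogradeSign` is
#'   overridden per axon by the metadata.
#' @return list with `summary` (one row per axon), `trackMetrics` (named
#'   list of per-track metrics) and `rejected` (data.frame
#'   `track_id, reason`).
#' @export
classifyCohort <- function(tracks, metadata, cfg = TrackMotionConfig()) {
  stopifnot(all(c("axon_id", "track_id", "frame", "x_px") %in% names(tracks)),
            all(c("axon_id", "kymo_length_um") %in% names(metadata)))
  if (anyDuplicated(metadata$axon_id))
    stop("duplicate axon_id in metadata")
  axonIds <- sort(unique(as.character(metadata$axon_id)))
  unknown <- setdiff(unique(tracks$axon_id), metadata$axon_id)
  if (length(unknown))
    stop("tracks reference axons absent from metadata: ",
         paste(unknown, collapse = ", "))
  rejected <- data.frame(track_id = character(), reason = character())
  allMetrics <- list()
  rows <- vector("list", length(axonIds))
  for (k in seq_along(axonIds)) {
    aid <- axonIds[k]
    md <- metadata[metadata$axon_id == aid, ]
    acfg <- cfg
    if (!is.null(md$anterograde_sign))
      acfg@anterogradeSign <- md$anterograde_sign[1L]
    at <- tracks[tracks$axon_id == aid, ]
    mlist <- list()
    for (tid in sort(unique(as.character(at$track_id)))) {
      tr <- at[at$track_id == tid, ]
      tr <- tr[order(tr$frame), ]
      if (nrow(tr) < acfg@minTrackFrames) {
        rejected <- rbind(rejected,
          data.frame(track_id = tid,
                     reason = sprintf("only %d frames (< %d)", nrow(tr),
                                      as.integer(acfg@minTrackFrames))))
        next
      }
      tr$track_id <- tid
      mlist[[tid]] <- classifyTrack(tr, acfg)
    }
    allMetrics <- c(allMetrics, mlist)
    rows[[k]] <- summarizeAxon(mlist, md$kymo_length_um[1L], acfg,
                               axonId = aid)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    summarizeAxon(list(), 1)[0, ]
  rownames(summary) <- NULL
  list(summary = summary, trackMetrics = allMetrics, rejected = rejected)
}
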