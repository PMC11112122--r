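cfg <- TrackMotionConfig()

test_that("movement flags implement the changed/stayed-the-same test", {
  still <- trackDf(rep(100L, 180))
  f <- binarizeMotion(still, cfg)
  expect_length(f$moving, 179)
  expect_false(any(f$moving))

  adv <- trackDf(0:20)
  f <- binarizeMotion(adv, cfg)
  expect_true(all(f$moving))
  expect_true(all(f$sign == 1))

  set.seed(42)
  for (k in 1:20) {
    x <- randomTrack(40)
    f <- binarizeMotion(trackDf(x), cfg)
    expect_identical(f$moving, abs(diff(x)) > 0.5)
    expect_identical(f$sign, sign(diff(x)))
  }
})

test_that("non-contiguous frames are rejected, not interpolated", {
  tr <- data.frame(track_id = "t", frame = c(0:10, 12:25), x_px = 0)
  expect_error(binarizeMotion(tr, cfg), "contiguous")
})

test_that("segmentation applies the five-frame run/pause cutoffs", {
  # 4 moving intervals then 10 still: oscillation + pause
  x <- c(0:4, rep(4L, 10))
  seg <- segmentStates(binarizeMotion(trackDf(x), cfg), cfg)
  expect_identical(seg$state, c("oscillation", "pause"))
  expect_identical(seg$n_intervals, c(4L, 10L))

  # 20 moving intervals, all positive: one anterograde run
  seg <- segmentStates(binarizeMotion(trackDf(0:20), cfg), cfg)
  expect_identical(seg$state, "run")
  expect_identical(seg$direction, "anterograde")
  expect_identical(seg$n_intervals, 20L)
})

test_that("segmentation equals the brute-force oracle on random tracks", {
  set.seed(7)
  for (k in 1:1000) {
    x <- randomTrack(sample(10:50, 1L))
    seg <- segmentStates(binarizeMotion(trackDf(x), cfg), cfg)
    expect_identical(segmentsToLabels(seg, length(x) - 1L),
                     oracleLabels(x))
  }
})

test_that("segments tile every track without gaps or overlaps", {
  set.seed(8)
  for (k in 1:200) {
    x <- randomTrack(sample(10:60, 1L))
    seg <- segmentStates(binarizeMotion(trackDf(x), cfg), cfg)
    expect_identical(sum(seg$n_intervals), length(x) - 1L)
    expect_identical(seg$start_frame[1L], 0L)
    expect_identical(seg$end_frame[nrow(seg)], length(x) - 2L)
    if (nrow(seg) > 1L)
      expect_identical(seg$start_frame[-1L], seg$end_frame[-nrow(seg)] + 1L)
  }
})

test_that("run metrics follow the stated calibration arithmetic", {
  # +1 px/frame for 20 frames at 0.175 um/px, 1 s/frame
  m <- classifyTrack(trackDf(0:20), cfg)
  expect_false(m$is_stationary)
  expect_equal(nrow(m$segments), 1L)
  expect_equal(m$segments$distance_um, 3.5)
  expect_equal(m$segments$mean_speed_um_s, 0.175)
  expect_equal(m$mean_run_distance_um[["antero"]], 3.5)
  expect_equal(m$net_displacement_um, 3.5)
  expect_equal(m$net_direction, "anterograde")
})

test_that("net displacement threshold is 5 px = 0.875 um", {
  expect_equal(cfg@netDispThresholdPx * cfg@pixelSizeUm, 0.875)
  # mobile track ending 4 px from its start: net direction none
  x <- c(0:10, 10:4, rep(4L, 10))   # run out, run back, pause
  m <- classifyTrack(trackDf(x), cfg)
  expect_false(m$is_stationary)
  expect_equal(x[length(x)] - x[1L], 4L)
  expect_equal(m$net_direction, "none")
  # one more pixel and it classifies
  x2 <- c(0:10, 10:5, rep(5L, 10))
  m2 <- classifyTrack(trackDf(x2), cfg)
  expect_equal(m2$net_direction, "anterograde")
})

test_that("stationary tracks report no pauses and no net direction", {
  m <- classifyTrack(trackDf(rep(10L, 50)), cfg)
  expect_true(m$is_stationary)
  expect_length(m$pause_durations_s, 0)
  expect_equal(m$net_direction, "none")
  # oscillation-only track is also stationary (no runs)
  x <- c(rep(5L, 10), 6L, 5L, rep(5L, 10))
  m2 <- classifyTrack(trackDf(x), cfg)
  expect_true(m2$is_stationary)
})

test_that("short tracks are rejected", {
  expect_error(classifyTrack(trackDf(0:10), cfg), "minTrackFrames")
})

test_that("mirroring a track swaps directions and negates net displacement", {
  set.seed(9)
  for (k in 1:50) {
    x <- randomTrack(60)
    m <- classifyTrack(trackDf(x), cfg)
    mm <- classifyTrack(trackDf(-x), cfg)
    expect_identical(m$n_runs_antero, mm$n_runs_retro)
    expect_identical(m$n_runs_retro, mm$n_runs_antero)
    expect_equal(m$net_displacement_um, -mm$net_displacement_um)
    expect_equal(m$mean_run_distance_um[["antero"]],
                 mm$mean_run_distance_um[["retro"]])
    expect_equal(m$mean_speed_um_s[["retro"]],
                 mm$mean_speed_um_s[["antero"]])
    expect_equal(sort(m$segments$duration_s), sort(mm$segments$duration_s))
  }
})

test_that("per-axon summary aggregates match their definitions", {
  mk <- function(x) classifyTrack(trackDf(x), cfg)
  stat <- replicate(4, mk(rep(7L, 30)), simplify = FALSE)
  mob <- replicate(6, mk(c(0:14, rep(14L, 15))), simplify = FALSE)
  s <- summarizeAxon(c(stat, mob), kymoLengthUm = 35)
  expect_equal(s$pct_stationary, 40)
  expect_equal(s$n_tracks, 10L)
  # 7 tracks on a 35 um kymograph would be 2.0 per 10 um
  expect_equal(summarizeAxon(c(stat, mob)[1:7], 35)$vesicles_per_10um, 2.0)
  # empty input
  s0 <- summarizeAxon(list(), 35)
  expect_equal(s0$n_tracks, 0L)
  expect_true(is.na(s0$pct_stationary))
})

test_that("cohort classification composes per-axon summaries and is order invariant", {
  co <- simulateCohort(3, 8, MotionModelParams(), seed = 5)
  res <- classifyCohort(co$tracks, co$metadata)
  expect_equal(nrow(res$summary), 3L)

  # single-axon row equals summarizeAxon of its tracks
  a1 <- co$tracks[co$tracks$axon_id == "axon001", ]
  ms <- lapply(split(a1, a1$track_id), classifyTrack, cfg = cfg)
  s1 <- summarizeAxon(ms, co$metadata$kymo_length_um[1L], cfg,
                      axonId = "axon001")
  expect_equal(res$summary[1L, ], s1)

  # shuffled input rows give the identical summary
  set.seed(1)
  shuf <- co$tracks[sample(nrow(co$tracks)), ]
  res2 <- classifyCohort(shuf, co$metadata[3:1, ])
  expect_equal(res2$summary, res$summary)

  # empty cohort gives an empty table
  res0 <- classifyCohort(co$tracks[0, ], co$metadata[0, ])
  expect_equal(nrow(res0$summary), 0L)

  # short tracks land in the rejection log
  short <- data.frame(axon_id = "axon001", track_id = "shorty",
                      frame = 0:9, x_px = 0L)
  res3 <- classifyCohort(rbind(co$tracks, short), co$metadata)
  expect_true("shorty" %in% res3$rejected$track_id)
})
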