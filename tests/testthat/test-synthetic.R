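test_that("empty and degenerate simulations behave", {
  sim <- simulateTracks(MotionModelParams(nParticles = 0), seed = 1)
  expect_equal(nrow(sim$tracks), 0L)
  expect_length(sim$truth$states, 0)

  # forced stationarity: constant x over all 180 frames
  sim <- simulateTracks(MotionModelParams(nParticles = 5, pStationary = 1),
                        seed = 99)
  for (id in unique(sim$tracks$track_id)) {
    x <- sim$tracks$x_px[sim$tracks$track_id == id]
    expect_length(x, 180)
    expect_equal(length(unique(x)), 1L)
  }
  expect_true(all(sim$truth$stationary$is_stationary))
})

test_that("invalid model parameters are refused", {
  expect_error(MotionModelParams(pStationary = 1.5), "probability")
  expect_error(MotionModelParams(nFrames = 10), "nFrames")
  expect_error(MotionModelParams(pauseMedianS = 2), "pause")
})

test_that("ground-truth run and pause blocks respect the 5-frame floors", {
  set.seed(123)
  for (k in 1:1000) {
    p <- MotionModelParams(
      nParticles = 1,
      nFrames = sample(20:120, 1L),
      pStationary = runif(1, 0, 0.8),
      runLengthMedianUm = c(antero = runif(1, 2, 10),
                            retro = runif(1, 2, 10)),
      runSpeedMedianUmS = c(antero = runif(1, 0.3, 1),
                            retro = runif(1, 0.3, 1)),
      pauseMedianS = runif(1, 6, 25),
      oscillationRate = runif(1, 0, 2))
    sim <- simulateTracks(p, seed = k)
    for (lab in sim$truth$states) {
      r <- rle(lab)
      expect_true(all(r$lengths[startsWith(r$values, "run")] >= 5))
      expect_true(all(r$lengths[r$values == "pause"] >= 5))
    }
  }
})

test_that("classifier per-interval labels equal ground truth on noiseless tracks", {
  sim <- simulateTracks(MotionModelParams(nParticles = 100), seed = 21)
  cfg <- TrackMotionConfig()
  for (id in names(sim$truth$states)) {
    tr <- sim$tracks[sim$tracks$track_id == id, ]
    seg <- classifyTrack(tr, cfg)$segments
    expect_identical(segmentsToLabels(seg, nrow(tr) - 1L),
                     sim$truth$states[[id]])
  }
})

test_that("every generator is bit-identical under the same seed", {
  p <- MotionModelParams(nParticles = 10)
  expect_identical(simulateTracks(p, seed = 5), simulateTracks(p, seed = 5))
  expect_identical(simulateMpsProfile(seed = 5)@values,
                   simulateMpsProfile(seed = 5)@values)
  expect_identical(simulateAisImage(4, seed = 5),
                   simulateAisImage(4, seed = 5))
  expect_identical(
    simulateAisMarkerProfile(noiseFrac = 0.05, seed = 5)@values,
    simulateAisMarkerProfile(noiseFrac = 0.05, seed = 5)@values)
  expect_identical(simulateColocTable(n = 50, noiseSigma = 3, seed = 5),
                   simulateColocTable(n = 50, noiseSigma = 3, seed = 5))
  sim <- simulateTracks(p, seed = 5)
  expect_identical(
    kymoImage(renderKymograph(sim$tracks, 512, noiseSigma = 10, seed = 2)),
    kymoImage(renderKymograph(sim$tracks, 512, noiseSigma = 10, seed = 2)))
  # and different seeds differ
  expect_false(identical(simulateTracks(p, seed = 5),
                         simulateTracks(p, seed = 6)))
})

test_that("kymograph rendering is geometric and superposable", {
  # one stationary particle, zero noise: constant vertical stripe
  tr <- data.frame(track_id = "a", frame = 0:29, x_px = 40L)
  k <- renderKymograph(tr, spacePx = 80, noiseSigma = 0)
  am <- apply(kymoImage(k), 1L, which.max)
  expect_true(all(am == 41))

  # one particle moving +1 px/frame: argmax advances by exactly 1
  tr <- data.frame(track_id = "a", frame = 0:29, x_px = 10:39)
  k <- renderKymograph(tr, spacePx = 80, noiseSigma = 0)
  expect_identical(diff(apply(kymoImage(k), 1L, which.max)),
                   rep(1L, 29))

  # superposition: union render = sum of single renders - background
  t1 <- data.frame(track_id = "a", frame = 0:29, x_px = 20L)
  t2 <- data.frame(track_id = "b", frame = 0:29, x_px = 55:26)
  kU <- renderKymograph(rbind(t1, t2), 80, noiseSigma = 0, background = 100)
  k1 <- renderKymograph(t1, 80, noiseSigma = 0, background = 100)
  k2 <- renderKymograph(t2, 80, noiseSigma = 0, background = 100)
  expect_equal(kymoImage(kU), kymoImage(k1) + kymoImage(k2) - 100)

  # out-of-bounds tracks are refused
  bad <- data.frame(track_id = "a", frame = 0:5, x_px = 79:84)
  expect_error(renderKymograph(bad, spacePx = 80), "spatial extent")
})

test_that("synthetic MPS lattice has the constructed peak spacing", {
  p <- simulateMpsProfile(spacingNm = 190, pxNm = 30, lengthUm = 10,
                          noiseFrac = 0, seed = 1)
  v <- profileValues(p)
  # local maxima spacing: 190/30 = 6.33 px, so gaps alternate 6 and 7 px
  # (peaks midway between samples give two-sample ties; take the tie's end)
  n <- length(v)
  pk <- which(v >= c(-Inf, v[-n]) & v > c(v[-1], -Inf))
  gaps <- diff(pk)
  expect_true(all(gaps %in% c(6L, 7L)))
  expect_equal(mean(gaps), 190 / 30, tolerance = 0.02)
  expect_error(simulateMpsProfile(spacingNm = 50, pxNm = 30), "undersampled")
  expect_error(simulateMpsProfile(lengthUm = 1), "10 lattice periods")
})

test_that("synthetic AIS images carry usable ground truth", {
  sim0 <- simulateAisImage(0, noiseSigma = 0, seed = 1)
  expect_equal(length(unique(as.vector(sim0$image))), 1L)
  expect_equal(nrow(detectPatches(sim0$image)), 0L)

  sim2 <- simulateAisImage(2, noiseSigma = 0, seed = 4)
  det <- detectPatches(sim2$image)
  expect_equal(nrow(det), 2L)
  for (i in 1:2) {
    d <- sqrt((det$x_px - sim2$truth$x_px[i])^2 +
              (det$y_px - sim2$truth$y_px[i])^2)
    expect_lt(min(d), 1)
  }
  expect_error(simulateAisImage(500, imageShape = c(32, 64)), "packing")
})

test_that("AIS marker profile edges follow the error-function construction", {
  # sharp-edge limit: rectangle of the stated extent
  p <- simulateAisMarkerProfile(trueLengthUm = 27.5, edgeSigmaUm = 0,
                                noiseFrac = 0, seed = 1)
  res <- measureAisLength(p, smoothingUm = 0)
  expect_true(res$detected)
  expect_equal(res$length_um, 27.5, tolerance = 0.1)

  # finite edges: crossing distance has the closed form L - 2*sigma*qnorm(f)
  sigma <- 1.2; f <- 0.33
  p <- simulateAisMarkerProfile(trueLengthUm = 27.5, edgeSigmaUm = sigma,
                                noiseFrac = 0, seed = 1)
  res <- measureAisLength(p, smoothingUm = 0, thresholdFraction = f)
  expect_equal(res$length_um, 27.5 - 2 * sigma * qnorm(f), tolerance = 0.05)
  expect_error(simulateAisMarkerProfile(trueLengthUm = 3, edgeSigmaUm = 1),
               "edgeSigmaUm")
})

test_that("noiseless coloc tables are recovered exactly", {
  tab <- simulateColocTable(n = 200, slope = 1578, intercept = 4156,
                            noiseSigma = 0, seed = 2)
  fit <- correlateIntensities(tab)
  expect_equal(fit$slope, 1578, tolerance = 1e-9)
  expect_equal(fit$intercept, 4156, tolerance = 1e-6)
  expect_equal(fit$spearman_r, 1)
})
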