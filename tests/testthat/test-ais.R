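test_that("autocorrelation is normalized and finds cosine periods", {
  pxNm <- 30
  n <- 400
  x <- (0:(n - 1)) * pxNm
  p <- IntensityProfile(cos(2 * pi * x / 190) + 2, spacing = pxNm,
                        unit = "nm")
  ac <- autocorrelateProfile(p, maxLagNm = 600)
  expect_equal(ac@values[1L], 1)
  expect_true(all(abs(ac@values) <= 1 + 1e-8))
  # maxima at 0, T, 2T up to one-pixel quantization
  expect_true(peakLagNm(ac) %in% c(180, 210))
  expect_error(autocorrelateProfile(
    IntensityProfile(rep(1, 100), 30, "nm")), "constant")
})

test_that("curve averaging returns pointwise mean and s.e.m.", {
  p1 <- simulateMpsProfile(seed = 1)
  p2 <- simulateMpsProfile(seed = 2)
  c1 <- autocorrelateProfile(p1)
  c2 <- autocorrelateProfile(p2)
  avg <- averageAutocorr(list(c1, c2))
  expect_equal(avg@values, (c1@values + c2@values) / 2)
  same <- averageAutocorr(list(c1, c1, c1))
  expect_equal(same@values, c1@values)
  expect_true(all(same@sem == 0))
  short <- new("AutocorrCurve", lagsNm = c(0, 30), values = c(1, 0.5),
               sem = numeric(0), peakLagNm = NA_real_)
  expect_error(averageAutocorr(list(c1, short)), "lag grids")

  # s.e.m. of the averaged curve shrinks like 1/sqrt(n)
  curves <- lapply(1:32, function(s)
    autocorrelateProfile(simulateMpsProfile(seed = s)))
  s8 <- mean(averageAutocorr(curves[1:8])@sem)
  s32 <- mean(averageAutocorr(curves)@sem)
  expect_equal(s8 / s32, 2, tolerance = 0.5)
})

test_that("period estimation recovers lattice spacings and rejects noise", {
  # lattice sweep: within one 30 nm pixel in at least 95% of replicates
  for (spacing in c(150, 190, 250)) {
    hits <- 0L
    for (s in 1:100) {
      p <- simulateMpsProfile(spacingNm = spacing, pxNm = 30, lengthUm = 10,
                              noiseFrac = 0.1, seed = s)
      est <- peakLagNm(autocorrelateProfile(p))
      if (!is.na(est) && abs(est - spacing) <= 30) hits <- hits + 1L
    }
    expect_gte(hits, 95)
  }

  # white noise: no qualifying side peak at a significance-level prominence
  nas <- 0L
  for (s in 1:100) {
    v <- withr::with_seed(s, rnorm(334))
    ac <- autocorrelateProfile(IntensityProfile(v, 30, "nm"))
    if (is.na(estimatePeriod(ac, minProminence = 0.3))) nas <- nas + 1L
  }
  expect_gte(nas, 95)

  # dominant first peak wins in a two-component signal: brute-force scan
  x <- (0:399) * 30
  v <- cos(2 * pi * x / 190) + 0.15 * cos(2 * pi * x / 400)
  ac <- autocorrelateProfile(IntensityProfile(v + 2, 30, "nm"),
                             maxLagNm = 800)
  # oracle: scan for the first local max after the first local min
  vv <- ac@values
  imin <- which(diff(sign(diff(vv))) == 2)[1L] + 1L
  imax <- which(diff(sign(diff(vv))) == -2) + 1L
  imax <- imax[imax > imin][1L]
  expect_equal(peakLagNm(ac), ac@lagsNm[imax])
})

test_that("monotone curves yield a missing period, not an error", {
  v <- exp(-(0:50) / 10)
  ac <- new("AutocorrCurve", lagsNm = (0:50) * 30, values = v / v[1L],
            sem = numeric(0), peakLagNm = NA_real_)
  expect_true(is.na(estimatePeriod(ac)))
})

test_that("patch detection matches the closed-form blob footprint", {
  sigma <- 3; A <- 1000; smooth <- 1
  sim <- simulateAisImage(2, patchSigmaPx = sigma, amplitude = A,
                          imageShape = c(64, 256), noiseSigma = 0, seed = 7)
  det <- detectPatches(sim$image, paThre = 0.6, areaThre = 0.7,
                       smoothingSigmaPx = smooth)
  expect_equal(nrow(det), 2L)

  # oracle: blurring a Gaussian blob gives a Gaussian with
  # sigma' = sqrt(sigma^2 + smooth^2) and amplitude A * sigma^2 / sigma'^2;
  # count grid pixels above paThre * peak (background is 0)
  s2 <- sigma^2 + smooth^2
  Aeff <- A * sigma^2 / s2
  r2max <- -2 * s2 * log(0.6)       # radius^2 where blob crosses threshold
  cnt <- function(cx, cy) {
    g <- expand.grid(x = 0:255, y = 0:63)
    sum((g$x - cx)^2 + (g$y - cy)^2 < r2max)
  }
  for (i in 1:2) {
    d2 <- (det$x_px - sim$truth$x_px[i])^2 + (det$y_px - sim$truth$y_px[i])^2
    j <- which.min(d2)
    expect_lt(sqrt(d2[j]), 1)
    expected <- cnt(sim$truth$x_px[i], sim$truth$y_px[i])
    expect_lt(abs(det$area_px[j] - expected), 0.15 * expected + 3)
  }
})

test_that("thresholded area grows monotonically as paThre is lowered", {
  sim <- simulateAisImage(4, seed = 9)
  areas <- sapply(seq(0.9, 0.3, by = -0.1), function(th)
    sum(detectPatches(sim$image, paThre = th, areaThre = 1e-6)$area_px))
  expect_true(all(diff(areas) >= 0))
  # and the two-blob count is stable across the whole pa_thre range
  sim2 <- simulateAisImage(2, seed = 10)
  for (th in seq(0.3, 0.9, by = 0.1))
    expect_equal(nrow(detectPatches(sim2$image, paThre = th)), 2L)
})

test_that("patch statistics are densities per 10 um and medians", {
  patches <- data.frame(patch_id = 1:12, x_px = 0, y_px = 0,
                        area_px = c(rep(20, 6), rep(30, 6)),
                        mean_intensity = 1)
  st <- patchStats(patches, roiLengthUm = 15)
  expect_equal(st$patches_per_10um, 8.0)
  expect_equal(st$median_area_px, 25)
  st0 <- patchStats(patches[0, ], roiLengthUm = 15)
  expect_equal(st0$patches_per_10um, 0)
  expect_true(is.na(st0$median_area_px))
})

test_that("AIS length is scale invariant and flags absent signal", {
  p <- simulateAisMarkerProfile(trueLengthUm = 24, edgeSigmaUm = 0.8,
                                noiseFrac = 0.02, seed = 3)
  r1 <- measureAisLength(p)
  p2 <- IntensityProfile(profileValues(p) * 37.5, spacing = p@spacing,
                         unit = "um")
  r2 <- measureAisLength(p2)
  expect_equal(r1$length_um, r2$length_um)
  expect_equal(r1$start_um, r2$start_um)

  z <- IntensityProfile(rep(0, 300), spacing = 0.09, unit = "um")
  rz <- measureAisLength(z)
  expect_false(rz$detected)
  expect_true(is.na(rz$length_um))
})
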