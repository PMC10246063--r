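# Offline characterization: scan resolution, re-binning, band profiles,
# double-Gaussian fits, profile residuals, hardness and linearity.

test_that("exactly linear scan data give zero residual RMS", {
  sr <- resolutionFromScan(1:10, 5 + 2 * (1:10))
  expect_equal(sr@residualRms, 0, tolerance = 1e-12)
  expect_equal(sr@slope, 2)
  expect_error(resolutionFromScan(rep(1, 5), 1:5), "degenerate")
})

test_that("injected 40 um centroid jitter is recovered as the scan resolution", {
  set.seed(71)
  pos <- seq_len(30)
  cent <- 10 + 1.3 * pos + rnorm(30, 0, 0.040 * 1.3)  # 40 um in mm via slope
  sr <- resolutionFromScan(pos, cent)
  expect_equal(sr@residualRmsMm, 0.040, tolerance = 0.3 * 0.040 / 0.040 * 0.3)
  expect_lt(abs(sr@residualRmsMm - 0.040) / 0.040, 0.30)
})

test_that("near-noise-free simulator scans resolve below 0.1 px equivalent", {
  sn <- testSensor(widthPx = 128, heightPx = 48, readNoiseE = 0)
  tr <- compactScene(sigmaMm = 2, yieldPE = 2e6, H = affineH(1, 64, 24))
  stream <- simulateScan(tr, sn, seq(-12, 12, by = 2), seed = 42)
  sr <- scanResolution(stream)
  expect_lt(sr@residualRms, 0.1)           # px
  expect_equal(sr@slope, 1, tolerance = 0.01)  # px per mm at this geometry
})

test_that("full simulator scan resolution lands at the tens-of-microns scale", {
  # CamE-like conditions scaled to a desk-size frame: sub-mm pixel pitch,
  # bright source
  sn <- testSensor(widthPx = 256, heightPx = 96, readNoiseE = 2.5)
  tr <- compactScene(sigmaMm = 1.5, yieldPE = 5e5, H = affineH(6, 128, 48))
  stream <- simulateScan(tr, sn, seq(-3, 3, by = 0.5), seed = 7)
  sr <- scanResolution(stream)
  # same order as the bench measurement (tens of um), not a hardware equality
  expect_lt(sr@residualRmsMm, 0.100)
  expect_gt(sr@residualRmsMm, 0.0001)
})

test_that("re-binning sums supercells, conserves total ADC and flags remainders", {
  fr <- rawFrame(matrix(1, 4, 4))
  r2 <- rebin(fr, 2)
  expect_equal(pixels(r2), matrix(4, 2, 2))
  expect_identical(pixels(rebin(fr, 1)), pixels(fr))
  set.seed(3)
  big <- rawFrame(matrix(rpois(48 * 48, 30), 48, 48))
  expect_equal(sum(pixels(rebin(big, 4))), sum(pixels(big)))
  expect_false(frameMeta(rebin(big, 4))$rebin$remainderDropped)
  odd <- rebin(rawFrame(matrix(1, 5, 5)), 2)
  expect_true(frameMeta(odd)$rebin$remainderDropped)
  expect_equal(dim(pixels(odd)), c(2L, 2L))
  expect_error(rebin(fr, 0), "positive")
})

test_that("2x2 re-binning degrades the scan resolution only mildly", {
  # the bench resolution floor is extrinsic (source positioning jitter), so
  # coarser binning barely matters while the spot shares charge over many
  # pixels; emulate with a 40 um jitter of the true source position
  sn <- testSensor(widthPx = 256, heightPx = 96)
  set.seed(61)
  pos <- seq(-3, 3, by = 0.5)
  truePos <- pos + rnorm(length(pos), 0, 0.040)
  frames <- lapply(seq_along(pos), function(i) {
    tr <- compactScene(sigmaMm = 1, yieldPE = 3e5, H = affineH(6, 128, 48),
                       centerMm = c(truePos[i], 0))
    fr <- renderFrame(tr, sn, seed = 190 + i)
    fr@meta$commandedMm <- pos[i]
    fr
  })
  stream <- FrameStream(frames)
  # box sized to cover +-2.7 sigma of the 6 px spot so the aperture cut
  # is mild in both binnings
  sr1 <- scanResolution(stream, boxPx = 33)
  binned <- FrameStream(lapply(frames, function(f) {
    b <- rebin(f, 2); b@meta$commandedMm <- f@meta$commandedMm; b
  }))
  sr2 <- scanResolution(binned, boxPx = 33)
  expect_equal(sr1@residualRmsMm, 0.040, tolerance = 0.5)
  expect_lt(abs(sr2@residualRmsMm / sr1@residualRmsMm - 1), 0.10)
})

test_that("band profiles project uniform and Gaussian images correctly", {
  uni <- bandProfile(rawFrame(matrix(7, 32, 64)), bandPx = 10)
  expect_equal(uni$intensity, rep(7, 64))
  one <- bandProfile(rawFrame(matrix(1:32, 32, 64, byrow = FALSE)),
                     bandPx = 1, centerPx = 4)
  expect_equal(one$intensity, rep(5, 64))  # single row 5 (0-based 4)
  expect_error(bandProfile(rawFrame(matrix(1, 8, 8)), bandPx = 20), "outside")
  # Gaussian spot projects to the analytic profile within shot noise
  sn <- testSensor(readNoiseE = 0)
  tr <- compactScene(yieldPE = 3e5, sigmaMm = 3)
  fr <- subtractPedestal(renderFrame(tr, sn, seed = 23))
  prof <- bandProfile(fr, bandPx = 5, centerPx = 48)
  expect_equal(prof$x[which.max(prof$intensity)], 48, tolerance = 1)
  fitted <- fitDoubleGaussian(prof$x, prof$intensity)
  expect_true(fitted$converged)
  expect_equal(fitted$profile@sigmaN, 3, tolerance = 0.05)
})

test_that("double-Gaussian fits recover noiseless clinical-shape parameters within 1%", {
  truth <- DoubleGaussianProfile(0, 0.92, 2.11, 0.106, 26.2)
  x <- seq(-60, 60, by = 0.25)
  fit <- fitDoubleGaussian(x, evalProfile(truth, x))
  expect_true(fit$converged)
  p <- fit$profile
  expect_equal(p@aN, 0.92, tolerance = 0.01)
  expect_equal(p@sigmaN, 2.11, tolerance = 0.01)
  expect_equal(p@aW, 0.106, tolerance = 0.01)
  expect_equal(p@sigmaW, 26.2, tolerance = 0.01)
  expect_lt(fit$rmsPctPeak, 0.01)
})

test_that("a single-Gaussian input is fit without a spurious tail", {
  x <- seq(-20, 20, by = 0.1)
  y <- exp(-x^2 / (2 * 2^2))
  fit <- fitDoubleGaussian(x, y)
  expect_true(fit$converged)
  # nested model: the fitted curve reproduces the input essentially exactly
  expect_lt(fit$rmsPctPeak, 0.1)
  yhat <- evalProfile(fit$profile, x)
  expect_lt(max(abs(yhat - y)), 1e-3)
})

test_that("profile residual RMS measures relative differences and ignores scale", {
  x <- seq(-40, 40, by = 0.2)
  p1 <- data.frame(x = x, intensity = exp(-x^2 / (2 * 2^2)))
  expect_equal(profileResidualRms(p1, p1), 0)
  scaled <- p1; scaled$intensity <- 1.02 * scaled$intensity
  expect_equal(profileResidualRms(p1, scaled), 0, tolerance = 1e-12)
  # constant offset of 1% of peak: RMS ~ 1% (profile is near zero over most
  # of the axis, so normalization barely distorts the offset)
  offset <- p1; offset$intensity <- offset$intensity + 0.01
  expect_equal(profileResidualRms(p1, offset), 1, tolerance = 0.08)
  expect_error(profileResidualRms(p1, data.frame(x = x + 1000, intensity = p1$intensity)),
               "disjoint")
  # the two clinical-shape parameter sets differ at the sub-percent level
  film <- DoubleGaussianProfile(0, 0.90, 2.18, 0.113, 30)
  hm <- DoubleGaussianProfile(0, 0.92, 2.11, 0.106, 26.2)
  xs <- seq(-60, 60, by = 0.25)
  rms <- profileResidualRms(data.frame(x = xs, intensity = evalProfile(hm, xs)),
                            data.frame(x = xs, intensity = evalProfile(film, xs)))
  expect_lt(rms, 2)   # order of the published half-percent residual
  expect_gt(rms, 0.05)
})

test_that("hardness R cancels common drifts exactly and finds zero slope when constant", {
  doses <- seq(0, 200, by = 10)
  hr <- hardnessAnalysis(doses * 30, doses, rep(320, 21), rep(50, 21))
  expect_equal(hr@slopePerKGy, 0, tolerance = 1e-15)
  expect_equal(hr@R, rep(1, 21))
  # common multiplicative drift leaves R untouched
  drift <- 1 + 0.3 * sin(seq(0, 3, length.out = 21))
  As <- 320 * drift * (1 - 0.00025 * doses)
  Acon <- 50 * drift
  hr2 <- hardnessAnalysis(doses * 30, doses, As, Acon)
  expect_equal(hr2@slopePerKGy, -0.00025, tolerance = 1e-10)
  expect_error(hardnessAnalysis(1:3, 0:2, c(0, 1, 1), c(1, 1, 1)), "zero")
})

test_that("linearity analysis flags a 6% low point without distorting the fit", {
  dpp <- c(0.28, 0.55, 1.07, 2.29, 3.39, 4.24, 7.9)
  sig <- 400 * dpp
  lr <- linearityAnalysis(dpp, sig)
  expect_equal(lr@deviation, rep(0, 7), tolerance = 1e-12)
  sig2 <- sig; sig2[7] <- 0.94 * sig[7]
  lr2 <- linearityAnalysis(dpp, sig2, fitMax = 4.5)
  expect_equal(lr2@deviation[7], -0.06, tolerance = 1e-9)
  expect_equal(lr2@deviation[1:6], rep(0, 6), tolerance = 1e-9)
})

test_that("a simulated charge sweep is linear within counting noise", {
  # pulse charges follow the measured sweep; signal = integrated frame ADC
  charges <- c(0.11, 0.22, 0.43, 0.92, 1.36, 1.70, 3.2)  # nC
  gcPerNc <- 4e4  # PE per nC, desk-scale optical gain
  sn <- testSensor(readNoiseE = 0)
  sig <- vapply(seq_along(charges), function(i) {
    tr <- compactScene(yieldPE = charges[i] * gcPerNc, sigmaMm = 2)
    sum(pixels(renderFrame(tr, sn, seed = 800 + i)) - sn@pedestalAdc)
  }, numeric(1))
  dpp <- vapply(charges, function(q) dosePerPulse(FluenceDose(q * 0.37 / 0.304, 2.0)),
                numeric(1))
  lr <- linearityAnalysis(dpp, sig)
  expect_lt(max(abs(lr@deviation)), 0.03)
})

test_that("thickness-normalized signal ratio reproduces the bench comparison", {
  expect_equal(thicknessNormalizedRatio(237, 0.43, 97, 1.25), 7.1,
               tolerance = 0.01)
  expect_equal(thicknessNormalizedRatio(100, 1, 100, 1), 1)
  expect_error(thicknessNormalizedRatio(1, 0, 1, 1), "thicknessA")
})
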