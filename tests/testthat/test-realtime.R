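# Per-frame pipeline: pedestal subtraction, beam finding, weighted moments,
# box refinement, plan comparison, interlock and latency bookkeeping.

test_that("pedestal subtraction removes the baseline and clamps negatives", {
  ped <- matrix(100, 16, 16)
  expect_equal(pixels(subtractPedestal(rawFrame(ped, 100), ped)),
               matrix(0, 16, 16))
  expect_equal(pixels(subtractPedestal(rawFrame(ped + 7, 100), ped)),
               matrix(7, 16, 16))
  expect_error(subtractPedestal(rawFrame(ped, 100), matrix(0, 4, 4)), "shape")
})

test_that("averaging dark frames shrinks the pedestal error by sqrt(n)", {
  sn <- testSensor(widthPx = 64, heightPx = 64)
  tr <- compactScene(yieldPE = 0)
  darks <- lapply(1:10, function(s) renderFrame(tr, sn, seed = 100 + s))
  ped <- buildPedestal(darks)
  err <- ped - sn@pedestalAdc
  noiseAdc <- sn@readNoiseE * sn@adcPerPE
  expect_lt(sd(as.vector(err)), 1.5 * noiseAdc / sqrt(10))
})

test_that("beam finding rejects noise-only frames at k = 5", {
  sn <- testSensor(widthPx = 64, heightPx = 64)
  tr <- compactScene(yieldPE = 0)
  hits <- sum(vapply(1:100, function(s) {
    fr <- subtractPedestal(renderFrame(tr, sn, seed = 200 + s))
    !is.null(findBeam(fr, kSigma = 5))
  }, logical(1)))
  expect_lt(hits, 10)
})

test_that("beam finding returns the component containing the true peak", {
  sn <- testSensor()
  tr <- compactScene(yieldPE = 1e5, sigmaMm = 2, centerMm = c(5, -8))
  fr <- subtractPedestal(renderFrame(tr, sn, seed = 17))
  region <- findBeam(fr)
  expect_false(is.null(region))
  peak <- which(pixels(fr) == max(pixels(fr)), arr.ind = TRUE)[1, ]
  expect_true(any(region[, 1] == peak[1] & region[, 2] == peak[2]))
})

test_that("of two spots the larger-integral component wins", {
  px <- matrix(0, 64, 64)
  px[10:14, 10:14] <- 200   # integral 5000
  px[40:44, 40:44] <- 100   # integral 2500
  region <- findBeam(rawFrame(px), noiseSigma = 1)
  expect_true(all(region[, 1] >= 10 & region[, 1] <= 14))
})

test_that("moments match hand-computable configurations", {
  px <- matrix(0, 300, 300)
  px[201, 101] <- 500  # 0-based (100, 200)
  m <- measureBeam(rawFrame(px), findBeam(rawFrame(px), noiseSigma = 1))
  expect_equal(m@centroidPx, c(100, 200))
  expect_equal(m@widthsPx, c(0, 0))
  # three equal pixels at x in {-1, 0, 1} relative: sigma_x = sqrt(2/3)
  px2 <- matrix(0, 32, 32)
  px2[16, 15:17] <- 100
  m2 <- measureBeam(rawFrame(px2), findBeam(rawFrame(px2), noiseSigma = 1),
                    refine = FALSE)
  expect_equal(m2@widthsPx[1], sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m2@widthsPx[2], 0)
  expect_equal(m2@integralAdc, 300)
})

test_that("pipeline moments equal a brute-force double loop over all pixels", {
  set.seed(55)
  for (rep in 1:5) {
    px <- matrix(rpois(256, 20), 16, 16)
    region <- as.matrix(expand.grid(row = 1:16, col = 1:16))
    m <- measureBeam(rawFrame(px), region, refine = FALSE)
    tot <- 0; sx <- 0; sy <- 0
    for (r in 1:16) for (c in 1:16) {
      w <- px[r, c]; tot <- tot + w
      sx <- sx + w * (c - 1); sy <- sy + w * (r - 1)
    }
    cx <- sx / tot; cy <- sy / tot
    vx <- 0; vy <- 0
    for (r in 1:16) for (c in 1:16) {
      vx <- vx + px[r, c] * (c - 1 - cx)^2
      vy <- vy + px[r, c] * (r - 1 - cy)^2
    }
    expect_equal(m@centroidPx, c(cx, cy), tolerance = 1e-12)
    expect_equal(m@widthsPx, sqrt(c(vx, vy) / tot), tolerance = 1e-12)
    expect_equal(m@integralAdc, tot)
  }
})

test_that("a simulated Gaussian spot is recovered to 0.1 px and 5% in width", {
  sn <- testSensor()
  sigmaMm <- 2
  tr <- compactScene(yieldPE = 1e5, sigmaMm = sigmaMm, centerMm = c(3.3, -4.7))
  truePx <- applyHomography(tr@homography, c(3.3, -4.7))
  for (s in 1:50) {
    fr <- subtractPedestal(renderFrame(tr, sn, seed = 300 + s))
    m <- measureBeam(fr, findBeam(fr))
    expect_lt(max(abs(m@centroidPx - truePx)), 0.1)
    expect_lt(max(abs(m@widthsPx - sigmaMm) / sigmaMm), 0.05)
  }
})

test_that("the refinement box ignores distant hot pixels and flags edge clipping", {
  px <- matrix(0, 64, 64)
  xs <- 28:36
  spot <- outer(exp(-(xs - 32)^2 / 8), exp(-(xs - 32)^2 / 8)) * 1000
  px[xs, xs] <- spot
  px[5, 60] <- 2000  # hot pixel far outside the box
  fr <- rawFrame(px)
  region <- rbind(as.matrix(expand.grid(row = xs, col = xs)), c(5, 60))
  m <- measureBeam(fr, region, boxPx = 17)
  expect_equal(m@centroidPx, c(31, 31), tolerance = 1e-6)  # 0-based center
  mNo <- measureBeam(fr, region, refine = FALSE)
  expect_gt(max(abs(mNo@centroidPx - 31)), 0.1)  # hot pixel biases unrefined
  # spot fully inside the box: refined equals unrefined on a clean frame
  pxc <- matrix(0, 64, 64); pxc[xs, xs] <- spot
  regc <- as.matrix(expand.grid(row = xs, col = xs))
  frc <- rawFrame(pxc)
  expect_equal(measureBeam(frc, regc, boxPx = 17)@centroidPx,
               measureBeam(frc, regc, refine = FALSE)@centroidPx,
               tolerance = 1e-9)
  # clipping at the frame edge is annotated
  pxe <- matrix(0, 32, 32); pxe[3:7, 3:7] <- 100
  mEdge <- refineBox(rawFrame(pxe), c(4, 4), boxPx = 17)
  expect_true("edge" %in% mEdge@flags)
  expect_error(refineBox(frc, c(30, 30), boxPx = 16), "odd")
})

test_that("centroid measurement is translation-equivariant", {
  sn <- testSensor(widthPx = 128, heightPx = 64)
  base <- compactScene(yieldPE = 2e5, sigmaMm = 2, H = affineH(1, 64, 32))
  measure <- function(dx) {
    tr <- base
    tr@beamX@center <- tr@beamX@center + dx
    fr <- subtractPedestal(renderFrame(tr, sn, seed = 77))
    measureBeam(fr, findBeam(fr))@centroidPx[1]
  }
  c0 <- measure(0)
  for (dx in c(-10, -3.5, 2.25, 7, 15))
    expect_equal(measure(dx) - c0, dx, tolerance = 0.05)
})

test_that("plan comparison triggers on the right reason with the residual bound", {
  H <- affineH(1, 48, 48)
  plan <- readPlanLUT(data.frame(x_mm = 0, y_mm = 0, dose_Gy = 0.17,
                                 dose_tol = 0.10, pos_tol_mm = 2,
                                 width_tol = 0.2), H)
  gc <- defaultGains()
  mk <- function(doseGy, xMm = 0) {
    new("BeamMeasurement", centroidPx = as.numeric(applyHomography(H, c(xMm, 0))),
        centroidMm = c(xMm, 0), widthsPx = c(2, 2),
        integralAdc = doseGy * gc@pePerGy * gc@adcPerPE, nPixels = 100L,
        frameIndex = 1L, valid = TRUE, flags = character())
  }
  okDec <- compareToPlan(mk(0.17), plan, gc)
  expect_false(okDec@triggered)
  expect_equal(okDec@residualDoseBoundGy, 100 * 50e-6)
  expect_equal(okDec@residualDoseBoundGy, 0.005)
  hi <- compareToPlan(mk(0.17 * 1.2), plan, gc)
  expect_true(hi@triggered); expect_equal(hi@reason, "dose_high")
  lo <- compareToPlan(mk(0.17 * 0.8), plan, gc)
  expect_true(lo@triggered); expect_equal(lo@reason, "dose_low")
  posd <- compareToPlan(mk(0.17, xMm = 5), plan, gc)
  expect_true(posd@triggered); expect_equal(posd@reason, "position")
})

test_that("the interlock is monotone: larger deviations never un-trigger", {
  H <- affineH(1, 48, 48)
  plan <- readPlanLUT(data.frame(x_mm = 0, y_mm = 0, dose_Gy = 1,
                                 dose_tol = 0.10, pos_tol_mm = 2,
                                 width_tol = 0.2), H)
  gc <- GainChain(1, 1)
  trig <- vapply(seq(1, 2, by = 0.05), function(f) {
    m <- new("BeamMeasurement", centroidPx = c(48, 48), centroidMm = c(0, 0),
             widthsPx = c(2, 2), integralAdc = f, nPixels = 10L,
             frameIndex = 1L, valid = TRUE, flags = character())
    compareToPlan(m, plan, gc)@triggered
  }, logical(1))
  expect_true(all(diff(as.integer(trig)) >= 0))
})

test_that("a plan-conformant stream processes without interlocks", {
  sn <- testSensor()
  doseGy <- 0.17
  tr <- compactScene(yieldPE = 2e5, sigmaMm = 2)
  # absolute calibration against a reference exposure of known dose
  gc <- calibrateGains(renderFrame(tr, sn, seed = 499), doseGy, sn@adcPerPE)
  frames <- lapply(1:5, function(i) renderFrame(tr, sn, seed = 500 + i,
                                                frameIndex = i))
  stream <- FrameStream(frames)
  plan <- readPlanLUT(data.frame(x_mm = 0, y_mm = 0, dose_Gy = doseGy,
                                 dose_tol = 0.10, pos_tol_mm = 2,
                                 width_tol = 0.5), tr@homography)
  res <- processStream(stream, plan, gc)
  expect_true(is.na(res$haltedAt))
  expect_length(res$measurements, 5)
  expect_false(any(vapply(res$decisions, function(d) d@triggered, logical(1))))
})

test_that("a mid-stream 5 mm beam jump halts the stream at the jump frame", {
  sn <- testSensor()
  doseGy <- 0.17
  mkTr <- function(x) compactScene(yieldPE = 2e5, sigmaMm = 2,
                                   centerMm = c(x, 0))
  gc <- calibrateGains(renderFrame(mkTr(0), sn, seed = 599), doseGy, sn@adcPerPE)
  frames <- c(lapply(1:3, function(i) renderFrame(mkTr(0), sn, seed = 600 + i)),
              lapply(4:6, function(i) renderFrame(mkTr(5), sn, seed = 600 + i)))
  stream <- FrameStream(frames)
  plan <- readPlanLUT(data.frame(x_mm = 0, y_mm = 0, dose_Gy = doseGy,
                                 dose_tol = 0.10, pos_tol_mm = 1,
                                 width_tol = 0.5), affineH(1, 48, 48))
  expect_warning(res <- processStream(stream, plan, gc), "interlock")
  expect_equal(res$haltedAt, 4L)
  expect_equal(res$decisions[[4]]@reason, "position")
  expect_length(res$decisions, 4)
})

test_that("post-halt residual dose stays within the configured bound", {
  sn <- testSensor(widthPx = 32, heightPx = 32)
  gc <- defaultGains()
  # pulse train at 1 kHz, 0.005 Gy per pulse -> 5 Gy/s delivered
  tr <- compactScene(yieldPE = 0.005 * gc@pePerGy, sigmaMm = 2,
                     H = affineH(1, 16, 16))
  ps <- PulseStructure(0.005, 1e-6, 1000, 0.01)
  stream <- simulatePulseTrain(tr, sn, ps, seed = 9)
  # a plan the beam violates from the start (wrong position)
  plan <- readPlanLUT(data.frame(x_mm = 10, y_mm = 10, dose_Gy = 0.005,
                                 dose_tol = 0.10, pos_tol_mm = 1,
                                 width_tol = 0.5), tr@homography)
  expect_warning(res <- processStream(stream, plan, gc,
                                      doseRateGyPerS = 5, responseTimeS = 2e-3),
                 "interlock")
  expect_equal(res$haltedAt, 1L)
  expect_lte(res$residualDoseGy, res$decisions[[1]]@residualDoseBoundGy * 1.001)
})

test_that("the latency ledger totals the tabulated stage ticks", {
  led <- LatencyLedger()
  expect_equal(totalTicks(led), 10700 + 68 + 76 + 47)
  expect_equal(totalTicks(led), 10891)
  expect_equal(totalLatencyUs(led), 43.564)
  expect_equal(round(totalLatencyUs(led), 1), 43.6)
  # 12500 ticks at 4 ns is the 50 us frame
  expect_equal(unname(led@ticks["frame"]) * led@tickNs / 1000, 50)
  custom <- LatencyLedger(c(frame = 12500, transfer = 10000, beamFinding = 50,
                            position = 50, widths = 50))
  expect_equal(totalTicks(custom), 10150)
})
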