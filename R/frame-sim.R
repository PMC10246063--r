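## Synthetic camera-frame generation with the monitor's optical and
## statistical structure: a separable double-Gaussian beam projected through
## the homography (Jacobian-weighted inverse mapping), inverse-square
## vignetting, Poisson photoelectron statistics, Gaussian readout noise, ADC
## quantization and clipping, and sparse single-pixel background hits.

# 0-based pixel-center coordinate grids of the frame actually read out
.pixelGrid <- function(sensor) {
  if (length(sensor@roi) == 4L) {
    x0 <- sensor@roi[1]; y0 <- sensor@roi[2]
    w <- sensor@roi[3]; h <- sensor@roi[4]
  } else {
    x0 <- 0L; y0 <- 0L; w <- sensor@widthPx; h <- sensor@heightPx
  }
  list(x = x0 + seq_len(w) - 1L, y = y0 + seq_len(h) - 1L, w = w, h = h)
}

# map every pixel center to the beam plane; return mm coordinate matrices
# [h x w] plus the absolute Jacobian determinant of the px -> mm map (mm^2
# of beam plane per px^2 of sensor), used as the density weight.
.inverseMapGrid <- function(truth, sensor) {
  g <- .pixelGrid(sensor)
  hinv <- solve(truth@homography@h)
  U <- matrix(g$x, nrow = g$h, ncol = g$w, byrow = TRUE)
  V <- matrix(g$y, nrow = g$h, ncol = g$w)
  W <- hinv[3, 1] * U + hinv[3, 2] * V + hinv[3, 3]
  X <- (hinv[1, 1] * U + hinv[1, 2] * V + hinv[1, 3]) / W
  Y <- (hinv[2, 1] * U + hinv[2, 2] * V + hinv[2, 3]) / W
  J <- abs(det(hinv)) / abs(W)^3
  list(X = X, Y = Y, J = J, grid = g)
}

#' Inverse-square vignetting factor at beam-plane points
#'
#' The dominant flat-field non-uniformity is the geometric 1/r^2 dependence
#' on the optical path length from the scintillator point to the lens. With
#' the lens at standoff distance d above the reference point, a point at
#' in-plane offset rho has r^2 = d^2 + rho^2 and factor d^2 / r^2; the
#' reference point itself has factor exactly 1.
#'
#' @param xyMm n x 2 matrix (or c(x, y)) of beam-plane positions (mm).
#' @param truth a \code{\linkS4class{SceneTruth}} carrying the vignette
#'   geometry (infinite standoff disables vignetting).
#' @return multiplier in (0, 1].
#' @export
vignetteFactor <- function(xyMm, truth) {
  xyMm <- listOrMat(xyMm)
  if (!is.finite(truth@vignetteDistMm)) return(rep(1, nrow(xyMm)))
  d2 <- truth@vignetteDistMm^2
  rho2 <- (xyMm[, 1] - truth@vignetteCenterMm[1])^2 +
          (xyMm[, 2] - truth@vignetteCenterMm[2])^2
  d2 / (d2 + rho2)
}

.vignetteGrid <- function(truth, X, Y) {
  if (!is.finite(truth@vignetteDistMm)) return(1)
  d2 <- truth@vignetteDistMm^2
  d2 / (d2 + (X - truth@vignetteCenterMm[1])^2 + (Y - truth@vignetteCenterMm[2])^2)
}

#' Expected photoelectrons per pixel for a scene
#'
#' The noise-free mean of the simulator: total yield x normalized separable
#' beam density evaluated at the inverse-mapped pixel center, weighted by
#' the Jacobian determinant of the pixel -> mm map and the vignette factor.
#'
#' @param truth a \code{SceneTruth}; @param sensor a \code{SensorModel}.
#' @return numeric matrix [rows = y, cols = x] of expected PE.
#' @export
expectedPE <- function(truth, sensor) {
  m <- .inverseMapGrid(truth, sensor)
  dens <- profileDensity(truth@beamX, m$X) * profileDensity(truth@beamY, m$Y)
  truth@yieldPE * dens * m$J * .vignetteGrid(truth, m$X, m$Y)
}

#' Relative local dose map (beam density normalized to the beam-core mean)
#'
#' Used by the pulse-train simulator to localize radiation damage. The
#' nominal dose per pulse refers to the beam core -- the charge enclosed by
#' the FW3QM divided by the core area -- so the map is the 2D beam density
#' divided by its mean over the FW3QM disc: a pixel whose mapped point sees
#' fraction f of the core-average dose accumulates fraction f of the
#' nominal cumulative dose (slightly above 1 at the very center, ~0 far
#' outside the beam).
#'
#' @inheritParams expectedPE
#' @keywords internal
relativeDoseMap <- function(truth, sensor) {
  m <- .inverseMapGrid(truth, sensor)
  dens <- profileDensity(truth@beamX, m$X) * profileDensity(truth@beamY, m$Y)
  dens / .coreMeanDensity(truth)
}

# mean 2D beam density over the FW3QM disc of the x-axis profile, computed
# on a fine polar-free cartesian grid around the beam center
.coreMeanDensity <- function(truth) {
  cx <- truth@beamX@center; cy <- truth@beamY@center
  xs <- seq(-6 * truth@beamX@sigmaN, 6 * truth@beamX@sigmaN, length.out = 2001)
  radius <- fw3qm(cx + xs, evalProfile(truth@beamX, cx + xs)) / 2
  g <- seq(-radius, radius, length.out = 201)
  inDisc <- outer(g^2, g^2, `+`) <= radius^2
  dens <- outer(profileDensity(truth@beamY, cy + g),
                profileDensity(truth@beamX, cx + g))
  mean(dens[inDisc])
}

#' Render one synthetic camera frame
#'
#' Pixel value = pedestal + round(gain x (Poisson(expected PE) +
#' Gaussian(0, read noise))) clipped to the ADC range, plus sparse
#' background hits (Poisson count of single-pixel impulses with an
#' exponential amplitude spectrum). Rendering is pure: the same seed and
#' inputs give a bit-identical frame.
#'
#' @param truth a \code{SceneTruth}.
#' @param sensor a \code{SensorModel}.
#' @param seed integer RNG seed (NULL leaves the RNG state alone).
#' @param yieldMap optional per-pixel multiplicative factor on the expected
#'   PE (e.g. a radiation-damage field).
#' @param yieldScale scalar multiplier on the total yield (pulse-to-pulse
#'   fluctuation).
#' @param frameIndex,pulseTag metadata passthrough.
#' @return a \code{\linkS4class{BeamFrame}}; if more than 1\% of pixels sit
#'   at the ADC ceiling the frame's \code{saturated} flag is set (with a
#'   warning).
#' @export
renderFrame <- function(truth, sensor, seed = NULL, yieldMap = NULL,
                        yieldScale = 1, frameIndex = NA_integer_,
                        pulseTag = NA_integer_) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- expectedPE(truth, sensor) * yieldScale
  if (!is.null(yieldMap)) {
    stopifnot(all(dim(yieldMap) == dim(lambda)))
    lambda <- lambda * yieldMap
  }
  npx <- length(lambda)
  pe <- if (truth@yieldPE * yieldScale > 0) rpois(npx, lambda) else numeric(npx)
  noise <- if (sensor@readNoiseE > 0) rnorm(npx, 0, sensor@readNoiseE) else 0
  adc <- sensor@pedestalAdc + round(sensor@adcPerPE * (pe + noise))
  adc <- matrix(adc, nrow = nrow(lambda))
  # sparse background hits: single-pixel impulses
  if (truth@bgHitRate > 0) {
    nhit <- rpois(1, truth@bgHitRate)
    if (nhit > 0) {
      idx <- sample.int(npx, nhit, replace = TRUE)
      adc[idx] <- adc[idx] + round(rexp(nhit, 1 / truth@bgHitAmpAdc))
    }
  }
  ceiling_adc <- 2^sensor@adcBits - 1
  adc <- pmin(pmax(adc, 0), ceiling_adc)
  sat <- mean(adc >= ceiling_adc - 1) > 0.01
  if (sat) warning("frame saturated: > 1% of pixels at the ADC ceiling")
  g <- .pixelGrid(sensor)
  BeamFrame(adc, meta = list(pedestalAdc = sensor@pedestalAdc,
                             adcBits = sensor@adcBits,
                             originPx = c(g$x[1], g$y[1]),
                             rngSeed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                             frameIndex = as.integer(frameIndex),
                             pulseTag = as.integer(pulseTag),
                             saturated = sat))
}

# shift the scene's beam center in beam-plane mm
.shiftBeam <- function(truth, dxMm = 0, dyMm = 0) {
  truth@beamX@center <- truth@beamX@center + dxMm
  truth@beamY@center <- truth@beamY@center + dyMm
  truth
}

#' Simulate a stepper-motor position scan
#'
#' One frame per commanded position, with the beam center translated in
#' beam-plane mm before projection (emulating the precision source stepped
#' across the scintillator). The commanded position is recorded in each
#' frame's metadata.
#'
#' @param truth,sensor scene and sensor.
#' @param positionsMm commanded beam-center x offsets (mm) relative to the
#'   scene's beam center; must stay inside the active area.
#' @param seed integer; frame i is rendered with seed + i.
#' @param axis "x" or "y".
#' @return a \code{\linkS4class{FrameStream}}.
#' @export
simulateScan <- function(truth, sensor, positionsMm, seed = 1L, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (!length(positionsMm)) return(FrameStream(list()))
  ctr <- if (axis == "x") truth@beamX@center else truth@beamY@center
  lim <- if (axis == "x") truth@activeAreaMm[1:2] else truth@activeAreaMm[3:4]
  pos <- ctr + positionsMm
  if (any(pos < lim[1] | pos > lim[2]))
    stop("commanded positions fall outside the scintillator active area")
  frames <- lapply(seq_along(positionsMm), function(i) {
    t2 <- if (axis == "x") .shiftBeam(truth, dxMm = positionsMm[i])
          else .shiftBeam(truth, dyMm = positionsMm[i])
    fr <- renderFrame(t2, sensor, seed = seed + i, frameIndex = i)
    fr@meta$commandedMm <- pos[i]
    fr
  })
  FrameStream(frames, meta = list(kind = "scan", axis = axis,
                                  commandedMm = pos, seed = seed))
}

#' Simulate a pulse train with dose ledger, fluctuations and radiation damage
#'
#' Emulates an extended irradiation: every pulse delivers the nominal dose
#' per pulse scaled by a Gaussian pulse-to-pulse fluctuation, and the
#' scintillator light yield degrades linearly with the locally accumulated
#' dose. The per-pixel yield factor is
#' 1 - rate x cumulative_kGy x relative local dose, clamped at 0 (with a
#' warning), where the relative local dose is the beam density normalized to
#' its peak -- so a control region far from the beam core degrades in
#' proportion to the small dose it actually receives.
#'
#' @param truth,sensor scene and sensor.
#' @param ps a \code{\linkS4class{PulseStructure}}; the number of pulses is
#'   repRateHz x durationS.
#' @param degradationRatePerKGy fractional signal loss per kGy at the beam
#'   core (e.g. 0.00025 for 0.025\%/kGy).
#' @param fluctuationRms relative RMS of the per-pulse yield/dose
#'   fluctuation (e.g. 0.016).
#' @param seed integer seed controlling fluctuations and every rendered frame.
#' @param recordEvery render a frame for every k-th pulse (the dose ledger
#'   still covers every pulse).
#' @return a \code{FrameStream} whose ledger has one row per pulse (pulse,
#'   timeS, dppGy, cumulativeKGy) and whose meta records the rendered pulse
#'   indices.
#' @export
simulatePulseTrain <- function(truth, sensor, ps, degradationRatePerKGy = 0,
                               fluctuationRms = 0, seed = 1L, recordEvery = 1L) {
  stopifnot(degradationRatePerKGy >= 0, fluctuationRms >= 0)
  nPulses <- as.integer(round(ps@repRateHz * ps@durationS))
  if (nPulses < 1) stop("pulse structure yields no pulses")
  set.seed(seed)
  fluct <- if (fluctuationRms > 0) rnorm(nPulses, 0, fluctuationRms) else numeric(nPulses)
  dpp <- ps@dppGy * (1 + fluct)
  ledger <- data.frame(pulse = seq_len(nPulses),
                       timeS = (seq_len(nPulses) - 1) / ps@repRateHz,
                       dppGy = dpp,
                       cumulativeKGy = cumsum(dpp) / 1000)
  recorded <- seq(1L, nPulses, by = as.integer(recordEvery))
  relDose <- if (degradationRatePerKGy > 0) relativeDoseMap(truth, sensor) else NULL
  clamped <- FALSE
  frames <- lapply(seq_along(recorded), function(k) {
    p <- recorded[k]
    priorKGy <- if (p == 1) 0 else ledger$cumulativeKGy[p - 1]
    ymap <- NULL
    if (!is.null(relDose)) {
      ymap <- 1 - degradationRatePerKGy * priorKGy * relDose
      if (any(ymap < 0)) { clamped <<- TRUE; ymap <- pmax(ymap, 0) }
    }
    fr <- renderFrame(truth, sensor, seed = seed + p,
                      yieldScale = 1 + fluct[p], yieldMap = ymap,
                      frameIndex = k, pulseTag = p)
    fr@meta$cumulativeKGy <- priorKGy
    fr
  })
  if (clamped)
    warning("degradation drove the local yield negative; clamped at 0")
  FrameStream(frames, ledger = ledger,
              meta = list(kind = "pulse_train", recordedPulses = recorded,
                          seed = seed, dppGy = ps@dppGy,
                          degradationRatePerKGy = degradationRatePerKGy,
                          fluctuationRms = fluctuationRms))
}
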