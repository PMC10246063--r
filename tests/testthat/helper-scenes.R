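# Shared fixture builders: small desk-scale sensors and scenes, all
# generated in code.

# affine mm -> px map: scale px/mm with an offset placing mm (0,0) at
# pixel (ox, oy)
affineH <- function(scale = 1, ox = 0, oy = 0)
  Homography(rbind(c(scale, 0, ox), c(0, scale, oy), c(0, 0, 1)))

# projective map emulating an oblique (~40 deg) camera view: y is
# foreshortened and the foreshortening varies with y
obliqueH <- function() {
  src <- rbind(c(-50, -50), c(50, -50), c(50, 50), c(-50, 50))
  dst <- rbind(c(10, 20), c(170, 20), c(150, 100), c(30, 100))
  estimateHomography(src, dst)
}

testSensor <- function(widthPx = 96, heightPx = 96, adcBits = 16,
                       readNoiseE = 2.5, pedestalAdc = 100)
  SensorModel(widthPx, heightPx, adcBits = adcBits, adcPerPE = 2.593,
              readNoiseE = readNoiseE, pedestalAdc = pedestalAdc)

# compact single-Gaussian-like beam fully contained in a 96 x 96 px frame
# at 1 px/mm (tail amplitude zero so total-count checks close)
compactScene <- function(yieldPE = 1e5, sigmaMm = 2.5, centerMm = c(0, 0),
                         H = affineH(1, 48, 48), bgHitRate = 0) {
  bx <- DoubleGaussianProfile(centerMm[1], aN = 1, sigmaN = sigmaMm,
                              aW = 0, sigmaW = 10 * sigmaMm)
  by <- DoubleGaussianProfile(centerMm[2], aN = 1, sigmaN = sigmaMm,
                              aW = 0, sigmaW = 10 * sigmaMm)
  SceneTruth(bx, by, yieldPE = yieldPE, homography = H, bgHitRate = bgHitRate,
             activeAreaMm = c(-48, 48, -48, 48))
}

# core + halo beam with the clinical-fit shape parameters
coreHaloScene <- function(yieldPE = 2e6, H = affineH(1, 40, 32),
                          activeAreaMm = c(-40, 120, -32, 32)) {
  bx <- DoubleGaussianProfile(0, aN = 0.92, sigmaN = 2.11, aW = 0.106,
                              sigmaW = 26.2)
  by <- DoubleGaussianProfile(0, aN = 0.92, sigmaN = 2.11, aW = 0.106,
                              sigmaW = 26.2)
  SceneTruth(bx, by, yieldPE = yieldPE, homography = H,
             activeAreaMm = activeAreaMm)
}

# synthetic flat-field frame: uniform screen emission modulated by the
# scene's vignette map, with Poisson + readout noise
flatFieldFrame <- function(sensor, H, peMean = 2000, vignetteDistMm = Inf,
                           vignetteCenterMm = c(0, 0), seed = 1) {
  set.seed(seed)
  d <- c(sensor@heightPx, sensor@widthPx)
  hinv <- solve(asMatrix(H))
  U <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  V <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  W <- hinv[3, 1] * U + hinv[3, 2] * V + hinv[3, 3]
  X <- (hinv[1, 1] * U + hinv[1, 2] * V + hinv[1, 3]) / W
  Y <- (hinv[2, 1] * U + hinv[2, 2] * V + hinv[2, 3]) / W
  vig <- if (is.finite(vignetteDistMm))
    vignetteDistMm^2 / (vignetteDistMm^2 + (X - vignetteCenterMm[1])^2 +
                          (Y - vignetteCenterMm[2])^2) else 1
  pe <- rpois(length(X), peMean * vig)
  adc <- sensor@pedestalAdc +
    round(sensor@adcPerPE * (pe + rnorm(length(X), 0, sensor@readNoiseE)))
  adc <- pmin(pmax(adc, 0), 2^sensor@adcBits - 1)
  BeamFrame(matrix(adc, d[1], d[2]),
            meta = list(pedestalAdc = sensor@pedestalAdc, originPx = c(0, 0)))
}

# plain synthetic frame from a pixel matrix (0-based origin)
rawFrame <- function(px, pedestalAdc = 0)
  BeamFrame(px, meta = list(pedestalAdc = pedestalAdc, originPx = c(0, 0)))

defaultGains <- function() GainChain(adcPerPE = 2800 / 1080, pePerGy = 1080 / 0.17)
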