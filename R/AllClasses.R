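#' @import methods
#' @importFrom stats rnorm rpois rexp lm coef predict approx sd mad median residuals quantile
#' @importFrom utils read.csv write.csv write.table head tail modifyList
NULL

## ---------------------------------------------------------------------------
## Analytic beam / dose model records
## ---------------------------------------------------------------------------

#' Double-Gaussian beam profile
#'
#' One-axis beam profile composed of a narrow primary core and a wide tail,
#' \deqn{f(x) = A_n e^{-(x-c)^2/2\sigma_n^2} + A_w e^{-(x-c)^2/2\sigma_w^2}.}
#' This is the standard core/halo description of collimated therapy beams.
#'
#' @slot center numeric(1), axis position of the peak (mm).
#' @slot aN numeric(1), amplitude of the narrow core (unitless, > 0).
#' @slot sigmaN numeric(1), RMS width of the narrow core (mm, > 0).
#' @slot aW numeric(1), amplitude of the wide tail (unitless, >= 0).
#' @slot sigmaW numeric(1), RMS width of the wide tail (mm, > sigmaN).
#' @export
setClass("DoubleGaussianProfile",
  representation(center = "numeric", aN = "numeric", sigmaN = "numeric",
                 aW = "numeric", sigmaW = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@sigmaN > 0)) msg <- c(msg, "sigmaN must be > 0")
    if (!(object@sigmaW > object@sigmaN))
      msg <- c(msg, "sigmaW must exceed sigmaN (wide tail wider than core)")
    if (!(object@aN > 0)) msg <- c(msg, "aN must be > 0")
    if (object@aW < 0) msg <- c(msg, "aW must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param center,aN,sigmaN,aW,sigmaW see slots of
#'   \code{\linkS4class{DoubleGaussianProfile}}.
#' @rdname DoubleGaussianProfile-class
#' @export
DoubleGaussianProfile <- function(center = 0, aN = 1, sigmaN = 1,
                                  aW = 0.1, sigmaW = 10 * sigmaN) {
  new("DoubleGaussianProfile", center = as.numeric(center), aN = as.numeric(aN),
      sigmaN = as.numeric(sigmaN), aW = as.numeric(aW), sigmaW = as.numeric(sigmaW))
}

setMethod("show", "DoubleGaussianProfile", function(object) {
  cat(sprintf(
    "DoubleGaussianProfile: center %.3g mm | core A=%.3g sigma=%.3g mm | tail A=%.3g sigma=%.3g mm\n",
    object@center, object@aN, object@sigmaN, object@aW, object@sigmaW))
})

#' Pulsed-beam time structure
#'
#' @slot dppGy dose per pulse (Gy).
#' @slot pulseWidthS pulse width (s, FWHM).
#' @slot repRateHz pulse repetition rate (Hz).
#' @slot durationS total irradiation time (s).
#' @export
setClass("PulseStructure",
  representation(dppGy = "numeric", pulseWidthS = "numeric",
                 repRateHz = "numeric", durationS = "numeric"),
  validity = function(object) {
    v <- c(object@dppGy, object@pulseWidthS, object@repRateHz, object@durationS)
    if (any(v < 0)) return("all pulse-structure fields must be >= 0")
    if (object@repRateHz > 0 && object@pulseWidthS > 1 / object@repRateHz)
      return("pulse width exceeds the pulse period")
    TRUE
  })

#' @param dppGy,pulseWidthS,repRateHz,durationS see slots.
#' @rdname PulseStructure-class
#' @export
PulseStructure <- function(dppGy, pulseWidthS, repRateHz, durationS) {
  new("PulseStructure", dppGy = as.numeric(dppGy),
      pulseWidthS = as.numeric(pulseWidthS),
      repRateHz = as.numeric(repRateHz), durationS = as.numeric(durationS))
}

#' Charge fluence and stopping power for dose-per-pulse conversion
#'
#' @slot fluenceNCcm2 charge fluence (nC/cm^2) delivered by one pulse.
#' @slot stoppingPower mass stopping power (MeV cm^2/g) of the medium.
#' @export
setClass("FluenceDose",
  representation(fluenceNCcm2 = "numeric", stoppingPower = "numeric"),
  validity = function(object) {
    if (object@fluenceNCcm2 < 0 || object@stoppingPower < 0)
      "fluence and stopping power must be >= 0" else TRUE
  })

#' @param fluenceNCcm2,stoppingPower see slots.
#' @rdname FluenceDose-class
#' @export
FluenceDose <- function(fluenceNCcm2, stoppingPower) {
  new("FluenceDose", fluenceNCcm2 = as.numeric(fluenceNCcm2),
      stoppingPower = as.numeric(stoppingPower))
}

#' Birks light-yield parameters
#'
#' @slot S photon conversion efficiency (photons per MeV scale).
#' @slot kB Birks constant, in the reciprocal units of dE/dx used.
#' @export
setClass("BirksParams",
  representation(S = "numeric", kB = "numeric"),
  validity = function(object) {
    if (!(object@S > 0)) return("S must be > 0")
    if (object@kB < 0) return("kB must be >= 0")
    TRUE
  })

#' @param S,kB see slots.
#' @rdname BirksParams-class
#' @export
BirksParams <- function(S, kB) new("BirksParams", S = as.numeric(S), kB = as.numeric(kB))

## ---------------------------------------------------------------------------
## Geometry / sensor / scene
## ---------------------------------------------------------------------------

#' Planar homography between the beam plane (mm) and sensor pixels
#'
#' 3x3 projective matrix with h[3,3] = 1, mapping beam-plane positions in mm
#' to sensor pixel coordinates (0-based, pixel centers at integers). The
#' oblique camera view of the scintillator induces such a map.
#'
#' @slot h 3x3 numeric matrix, h[3,3] == 1, invertible.
#' @slot rmsPx reprojection RMS (px) of the estimate, 0 for exact maps.
#' @export
setClass("Homography",
  representation(h = "matrix", rmsPx = "numeric"),
  validity = function(object) {
    if (!all(dim(object@h) == c(3, 3))) return("h must be 3x3")
    if (abs(object@h[3, 3] - 1) > 1e-12) return("h[3,3] must equal 1")
    if (abs(det(object@h)) < 1e-12) return("homography is singular")
    TRUE
  })

#' @param h 3x3 matrix (h[3,3] scaled to 1 on construction).
#' @param rmsPx reprojection RMS in pixels.
#' @rdname Homography-class
#' @export
Homography <- function(h = diag(3), rmsPx = 0) {
  h <- as.matrix(h)
  if (abs(h[3, 3]) < 1e-300) stop("h[3,3] must be nonzero")
  new("Homography", h = h / h[3, 3], rmsPx = as.numeric(rmsPx))
}

setMethod("show", "Homography", function(object) {
  cat("Homography (beam mm -> sensor px), reprojection RMS",
      format(object@rmsPx, digits = 3), "px\n")
  print(signif(object@h, 6))
})

#' Camera sensor model
#'
#' @slot widthPx,heightPx sensor dimensions in pixels.
#' @slot adcBits ADC depth (pixel values span 0 .. 2^adcBits - 1).
#' @slot adcPerPE gain, ADC counts per photoelectron.
#' @slot readNoiseE RMS readout noise in electrons.
#' @slot pedestalAdc baseline offset in ADC counts.
#' @slot roi integer(0) for full frame, else c(x0, y0, w, h) 0-based sub-window.
#' @export
setClass("SensorModel",
  representation(widthPx = "integer", heightPx = "integer", adcBits = "integer",
                 adcPerPE = "numeric", readNoiseE = "numeric",
                 pedestalAdc = "numeric", roi = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@adcPerPE > 0)) msg <- c(msg, "adcPerPE must be > 0")
    if (object@readNoiseE < 0) msg <- c(msg, "readNoiseE must be >= 0")
    if (length(object@roi) %in% c(0L, 4L)) {
      if (length(object@roi) == 4L) {
        x0 <- object@roi[1]; y0 <- object@roi[2]
        w <- object@roi[3]; h <- object@roi[4]
        if (x0 < 0 || y0 < 0 || x0 + w > object@widthPx || y0 + h > object@heightPx)
          msg <- c(msg, "roi must lie inside the sensor extent")
      }
    } else msg <- c(msg, "roi must be empty or c(x0, y0, w, h)")
    if (length(msg)) msg else TRUE
  })

#' @param widthPx,heightPx,adcBits,adcPerPE,readNoiseE,pedestalAdc,roi see slots.
#' @rdname SensorModel-class
#' @export
SensorModel <- function(widthPx, heightPx, adcBits = 12L, adcPerPE = 2.593,
                        readNoiseE = 2.5, pedestalAdc = 100, roi = integer()) {
  new("SensorModel", widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      adcBits = as.integer(adcBits), adcPerPE = as.numeric(adcPerPE),
      readNoiseE = as.numeric(readNoiseE), pedestalAdc = as.numeric(pedestalAdc),
      roi = as.integer(roi))
}

#' Electron-beam camera default ("CamE-like"): ~2 MP, 12-bit, 2.5 e read noise,
#' gain from the 2800 ADC / 1080 PE peak-signal correspondence.
#' @param widthPx,heightPx override the default pixel dimensions.
#' @export
camESensor <- function(widthPx = 1920L, heightPx = 1080L)
  SensorModel(widthPx, heightPx, adcBits = 12L, adcPerPE = 2800 / 1080,
              readNoiseE = 2.5, pedestalAdc = 100)

#' Proton-beam camera default ("CamP-like"): 1 MP sensor read out through a
#' 212x212 ROI (~45,000 px) at high frame rate, 15 e read noise.
#' @export
camPSensor <- function() {
  w <- 1024L; h <- 1024L; r <- 212L
  SensorModel(w, h, adcBits = 12L, adcPerPE = 1, readNoiseE = 15,
              pedestalAdc = 100,
              roi = c((w - r) %/% 2L, (h - r) %/% 2L, r, r))
}

setMethod("show", "SensorModel", function(object) {
  cat(sprintf("SensorModel: %d x %d px, %d-bit ADC, gain %.3f ADC/PE, read noise %.1f e, pedestal %.1f ADC\n",
              object@widthPx, object@heightPx, object@adcBits,
              object@adcPerPE, object@readNoiseE, object@pedestalAdc))
  if (length(object@roi) == 4L)
    cat(sprintf("  ROI: %d x %d at (%d, %d)\n", object@roi[3], object@roi[4],
                object@roi[1], object@roi[2]))
})

#' Ground-truth scene for the frame simulator
#'
#' @slot beamX,beamY per-axis \code{DoubleGaussianProfile} (separable beam).
#' @slot yieldPE total expected photoelectrons per frame from the beam.
#' @slot homography beam plane (mm) to sensor (px) map.
#' @slot vignetteCenterMm beam-plane point directly under the lens (mm).
#' @slot vignetteDistMm lens standoff distance (mm); Inf disables vignetting.
#' @slot bgHitRate expected sparse background pixel hits per frame.
#' @slot bgHitAmpAdc mean amplitude (ADC) of the exponential hit spectrum.
#' @slot activeAreaMm c(xmin, xmax, ymin, ymax) scintillator extent (mm).
#' @export
setClass("SceneTruth",
  representation(beamX = "DoubleGaussianProfile", beamY = "DoubleGaussianProfile",
                 yieldPE = "numeric", homography = "Homography",
                 vignetteCenterMm = "numeric", vignetteDistMm = "numeric",
                 bgHitRate = "numeric", bgHitAmpAdc = "numeric",
                 activeAreaMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@yieldPE < 0) msg <- c(msg, "yieldPE must be >= 0")
    if (object@bgHitRate < 0) msg <- c(msg, "bgHitRate must be >= 0")
    if (length(object@vignetteCenterMm) != 2) msg <- c(msg, "vignetteCenterMm must be length 2")
    if (length(object@activeAreaMm) != 4) msg <- c(msg, "activeAreaMm must be c(xmin,xmax,ymin,ymax)")
    if (length(msg)) msg else TRUE
  })

#' @param beamX,beamY,yieldPE,homography,vignetteCenterMm,vignetteDistMm see slots.
#' @param bgHitRate,bgHitAmpAdc,activeAreaMm see slots.
#' @rdname SceneTruth-class
#' @export
SceneTruth <- function(beamX, beamY, yieldPE, homography,
                       vignetteCenterMm = c(0, 0), vignetteDistMm = Inf,
                       bgHitRate = 0, bgHitAmpAdc = 50,
                       activeAreaMm = c(-50, 50, -50, 50)) {
  new("SceneTruth", beamX = beamX, beamY = beamY, yieldPE = as.numeric(yieldPE),
      homography = homography, vignetteCenterMm = as.numeric(vignetteCenterMm),
      vignetteDistMm = as.numeric(vignetteDistMm), bgHitRate = as.numeric(bgHitRate),
      bgHitAmpAdc = as.numeric(bgHitAmpAdc), activeAreaMm = as.numeric(activeAreaMm))
}

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: yield %.4g PE/frame, beam center (%.2f, %.2f) mm\n",
              object@yieldPE, object@beamX@center, object@beamY@center))
  cat(sprintf("  vignette standoff %s mm, background %.3g hits/frame\n",
              format(object@vignetteDistMm), object@bgHitRate))
})

## ---------------------------------------------------------------------------
## Frames and streams
## ---------------------------------------------------------------------------

#' One camera frame: a 2D grid of ADC counts plus acquisition metadata
#'
#' @slot pixels numeric matrix indexed [row, col]; row r, column c holds the
#'   pixel at 0-based sensor coordinates x = c - 1, y = r - 1.
#' @slot meta list: exposureS, frameIndex, pulseTag, pedestalAdc, rngSeed,
#'   adcBits, saturated, plus free-form entries.
#' @export
setClass("BeamFrame",
  representation(pixels = "matrix", meta = "list"),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (any(object@pixels < 0, na.rm = TRUE) &&
        !isTRUE(object@meta$pedestalSubtracted))
      return("raw ADC pixels must be >= 0")
    TRUE
  })

#' @param pixels,meta see slots.
#' @rdname BeamFrame-class
#' @export
BeamFrame <- function(pixels, meta = list()) {
  defaults <- list(exposureS = NA_real_, frameIndex = NA_integer_,
                   pulseTag = NA_integer_, pedestalAdc = 0, rngSeed = NA_integer_,
                   adcBits = NA_integer_, saturated = FALSE)
  meta <- modifyList(defaults, meta)
  new("BeamFrame", pixels = pixels, meta = meta)
}

setMethod("show", "BeamFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BeamFrame %d x %d px | pedestal %.1f ADC | frame %s%s\n",
              d[2], d[1], object@meta$pedestalAdc,
              format(object@meta$frameIndex),
              if (isTRUE(object@meta$saturated)) " | SATURATED" else ""))
  cat(sprintf("  ADC range [%.0f, %.0f], mean %.1f\n", min(object@pixels),
              max(object@pixels), mean(object@pixels)))
})

#' Ordered sequence of frames with a delivered-dose ledger
#'
#' @slot frames list of \code{BeamFrame}.
#' @slot ledger data.frame with one row per pulse: pulse, timeS, dppGy,
#'   cumulativeKGy (empty for streams without dose bookkeeping).
#' @slot meta list (sensor, truth summaries, seeds, recorded pulse indices).
#' @export
setClass("FrameStream",
  representation(frames = "list", ledger = "data.frame", meta = "list"))

#' @param frames,ledger,meta see slots.
#' @rdname FrameStream-class
#' @export
FrameStream <- function(frames, ledger = data.frame(), meta = list())
  new("FrameStream", frames = frames, ledger = ledger, meta = meta)

setMethod("show", "FrameStream", function(object) {
  cat(sprintf("FrameStream: %d frames", length(object@frames)))
  if (nrow(object@ledger))
    cat(sprintf(", %d pulses, %.4g kGy cumulative", nrow(object@ledger),
                max(object@ledger$cumulativeKGy)))
  cat("\n")
})

setMethod("length", "FrameStream", function(x) length(x@frames))
setMethod("[[", "FrameStream", function(x, i) x@frames[[i]])

## ---------------------------------------------------------------------------
## Calibration products
## ---------------------------------------------------------------------------

#' Flat-field correction matrix on a mm mesh over the beam plane
#'
#' Multiplicative per-cell corrections normalized to a reference cell, built
#' from a flat-field exposure; cells partially covered by the active-area
#' boundary are dropped (NA).
#'
#' @slot cells numeric matrix of corrections [row = y cell, col = x cell].
#' @slot meshMm cell size (mm).
#' @slot xCellsMm,yCellsMm cell-center coordinates (mm).
#' @slot refCell integer c(row, col) of the reference cell (correction == 1).
#' @slot homography the beam-plane/sensor map the mesh was built under.
#' @export
setClass("CorrectionMatrix",
  representation(cells = "matrix", meshMm = "numeric",
                 xCellsMm = "numeric", yCellsMm = "numeric",
                 refCell = "integer", homography = "Homography"),
  validity = function(object) {
    v <- object@cells[!is.na(object@cells)]
    if (any(v <= 0)) return("all corrections must be > 0")
    rc <- object@refCell
    if (abs(object@cells[rc[1], rc[2]] - 1) > 1e-9)
      return("correction at the reference cell must equal 1")
    TRUE
  })

setMethod("show", "CorrectionMatrix", function(object) {
  cat(sprintf("CorrectionMatrix: %d x %d cells at %.2f mm mesh, %d valid\n",
              nrow(object@cells), ncol(object@cells), object@meshMm,
              sum(!is.na(object@cells))))
  cat(sprintf("  corrections in [%.3f, %.3f], reference cell (%d, %d)\n",
              min(object@cells, na.rm = TRUE), max(object@cells, na.rm = TRUE),
              object@refCell[1], object@refCell[2]))
})

#' ADC -> photoelectron -> dose gain chain
#'
#' @slot adcPerPE ADC counts per photoelectron.
#' @slot pePerGy photoelectrons per Gy at the calibration geometry.
#' @export
setClass("GainChain",
  representation(adcPerPE = "numeric", pePerGy = "numeric"),
  validity = function(object) {
    if (!(object@adcPerPE > 0 && object@pePerGy > 0))
      "both gains must be > 0" else TRUE
  })

#' @param adcPerPE,pePerGy see slots.
#' @rdname GainChain-class
#' @export
GainChain <- function(adcPerPE, pePerGy)
  new("GainChain", adcPerPE = as.numeric(adcPerPE), pePerGy = as.numeric(pePerGy))

setMethod("show", "GainChain", function(object) {
  cat(sprintf("GainChain: %.4g ADC/PE, %.4g PE/Gy (%.4g ADC/Gy)\n",
              object@adcPerPE, object@pePerGy, object@adcPerPE * object@pePerGy))
})

## ---------------------------------------------------------------------------
## Real-time pipeline records
## ---------------------------------------------------------------------------

#' Per-frame beam measurement
#'
#' @slot centroidPx c(x, y), ADC-weighted centroid in 0-based pixels.
#' @slot centroidMm c(x, y) in the beam plane via the inverse homography
#'   (NA when no homography was supplied).
#' @slot widthsPx c(sigmaX, sigmaY), weighted second central moments (px).
#' @slot integralAdc summed pedestal-subtracted ADC over the beam region.
#' @slot nPixels number of pixels contributing.
#' @slot frameIndex index within the stream.
#' @slot valid logical.
#' @slot flags character annotations ("edge" when the refinement box clipped).
#' @export
setClass("BeamMeasurement",
  representation(centroidPx = "numeric", centroidMm = "numeric",
                 widthsPx = "numeric", integralAdc = "numeric",
                 nPixels = "integer", frameIndex = "integer",
                 valid = "logical", flags = "character"),
  validity = function(object) {
    if (any(object@widthsPx < 0, na.rm = TRUE)) return("widths must be >= 0")
    if (object@integralAdc < 0) return("integrated signal must be >= 0")
    TRUE
  })

setMethod("show", "BeamMeasurement", function(object) {
  cat(sprintf("BeamMeasurement: centroid (%.2f, %.2f) px", object@centroidPx[1],
              object@centroidPx[2]))
  if (!any(is.na(object@centroidMm)))
    cat(sprintf(" = (%.2f, %.2f) mm", object@centroidMm[1], object@centroidMm[2]))
  cat(sprintf("\n  widths (%.2f, %.2f) px, integral %.4g ADC over %d px%s\n",
              object@widthsPx[1], object@widthsPx[2], object@integralAdc,
              object@nPixels,
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})

#' Treatment-plan lookup table in sensor coordinates
#'
#' Planned dose / position / tolerance records. Positions are transformed to
#' sensor pixels once at load time, so per-frame comparison needs no image
#' transform.
#'
#' @slot records data.frame: xMm, yMm, doseGy, doseTol, posTolMm, widthTol,
#'   xPx, yPx.
#' @slot homography the map used for the transform.
#' @export
setClass("PlanLUT",
  representation(records = "data.frame", homography = "Homography"),
  validity = function(object) {
    need <- c("xMm", "yMm", "doseGy", "doseTol", "posTolMm", "widthTol", "xPx", "yPx")
    if (!all(need %in% names(object@records)))
      return(paste("plan records need columns:", paste(need, collapse = ", ")))
    if (any(object@records$doseTol <= 0) || any(object@records$posTolMm <= 0) ||
        any(object@records$widthTol <= 0))
      return("all tolerances must be > 0")
    TRUE
  })

setMethod("show", "PlanLUT", function(object) {
  cat(sprintf("PlanLUT: %d records, doses %.3g - %.3g Gy\n",
              nrow(object@records), min(object@records$doseGy),
              max(object@records$doseGy)))
})

#' Interlock decision for one frame
#'
#' @slot triggered logical.
#' @slot reason one of "none", "dose_high", "dose_low", "position", "width",
#'   "no_beam".
#' @slot frameIndex frame at which the decision was made.
#' @slot residualDoseBoundGy dose rate x interlock response interval: the
#'   maximum dose deliverable after the deviation before the beam stops.
#' @export
setClass("InterlockDecision",
  representation(triggered = "logical", reason = "character",
                 frameIndex = "integer", residualDoseBoundGy = "numeric"),
  validity = function(object) {
    ok <- c("none", "dose_high", "dose_low", "position", "width", "no_beam")
    if (!object@reason %in% ok)
      return(paste("reason must be one of:", paste(ok, collapse = ", ")))
    TRUE
  })

setMethod("show", "InterlockDecision", function(object) {
  cat(sprintf("InterlockDecision: %s (frame %d, reason %s, residual bound %.4g Gy)\n",
              if (object@triggered) "TRIGGERED" else "clear",
              object@frameIndex, object@reason, object@residualDoseBoundGy))
})

#' Per-stage processing-latency ledger in FPGA clock ticks
#'
#' Latency is modelled, not measured: stage durations are configuration
#' constants in 4 ns clock ticks. The frame itself spans 12500 ticks (50 us);
#' data transfer overlaps the next exposure and the analysis stages run
#' back-to-back after it, so the total processing latency is the transfer
#' plus the three analysis stages.
#'
#' @slot ticks named numeric: frame, transfer, beamFinding, position, widths.
#' @slot tickNs clock period in ns (default 4).
#' @export
setClass("LatencyLedger",
  representation(ticks = "numeric", tickNs = "numeric"),
  validity = function(object) {
    need <- c("frame", "transfer", "beamFinding", "position", "widths")
    if (!all(need %in% names(object@ticks)))
      return(paste("ticks needs entries:", paste(need, collapse = ", ")))
    if (any(object@ticks < 0)) return("tick counts must be >= 0")
    TRUE
  })

#' @param ticks named numeric vector of per-stage tick counts.
#' @param tickNs clock period (ns).
#' @rdname LatencyLedger-class
#' @export
LatencyLedger <- function(ticks = c(frame = 12500, transfer = 10700,
                                    beamFinding = 68, position = 76, widths = 47),
                          tickNs = 4) {
  new("LatencyLedger", ticks = ticks, tickNs = as.numeric(tickNs))
}

#' @param ledger a \code{LatencyLedger}.
#' @return total processing latency in ticks (transfer + analysis stages).
#' @rdname LatencyLedger-class
#' @export
totalTicks <- function(ledger)
  unname(sum(ledger@ticks[c("transfer", "beamFinding", "position", "widths")]))

#' @return total processing latency in microseconds.
#' @rdname LatencyLedger-class
#' @export
totalLatencyUs <- function(ledger) totalTicks(ledger) * ledger@tickNs / 1000

setMethod("show", "LatencyLedger", function(object) {
  cat("LatencyLedger (ticks @", object@tickNs, "ns):\n")
  print(object@ticks)
  cat(sprintf("  total processing: %d ticks = %.3f us\n", totalTicks(object),
              totalLatencyUs(object)))
})

## ---------------------------------------------------------------------------
## Characterization results
## ---------------------------------------------------------------------------

#' Stepper-scan resolution result
#'
#' @slot commandedMm commanded source positions (mm).
#' @slot centroids measured centroids (px or mm).
#' @slot slope,intercept linear least-squares fit of centroid vs position.
#' @slot residualRms RMS of fit residuals in centroid units.
#' @slot residualRmsMm the same converted to beam-plane mm via the slope.
#' @export
setClass("ScanResult",
  representation(commandedMm = "numeric", centroids = "numeric",
                 slope = "numeric", intercept = "numeric",
                 residualRms = "numeric", residualRmsMm = "numeric"),
  validity = function(object) {
    if (length(object@commandedMm) != length(object@centroids))
      return("commanded and centroid sequences must have equal length")
    if (length(object@commandedMm) < 3) return("need >= 3 scan points")
    TRUE
  })

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: %d points, slope %.4g, residual RMS %.4g (%.4g mm = %.1f um)\n",
              length(object@commandedMm), object@slope, object@residualRms,
              object@residualRmsMm, 1000 * object@residualRmsMm))
})

#' Radiation-hardness ratio-of-ratios result
#'
#' R(t) = (A_s(t)/A_s(0)) / (A_con(t)/A_con(0)): the beam-core amplitude
#' normalized to time zero, divided by the same for a low-dose control
#' region. Common multiplicative drifts (beam-current variation) cancel.
#'
#' @slot timeS,doseKGy,As,Acon input series (A in ADC).
#' @slot R the ratio-of-ratios sequence, R[1] == 1 by construction.
#' @slot slopePerKGy OLS slope of R vs cumulative dose (fraction per kGy).
#' @slot slopeSe standard error of the slope.
#' @export
setClass("HardnessResult",
  representation(timeS = "numeric", doseKGy = "numeric", As = "numeric",
                 Acon = "numeric", R = "numeric", slopePerKGy = "numeric",
                 slopeSe = "numeric"),
  validity = function(object) {
    n <- length(object@doseKGy)
    if (length(object@As) != n || length(object@Acon) != n || length(object@R) != n)
      return("series lengths must agree")
    if (abs(object@R[1] - 1) > 1e-12) return("R[1] must equal 1 by construction")
    TRUE
  })

setMethod("show", "HardnessResult", function(object) {
  cat(sprintf("HardnessResult: %d points over %.4g kGy, slope %.4g %%/kGy (SE %.2g)\n",
              length(object@R), max(object@doseKGy), 100 * object@slopePerKGy,
              100 * object@slopeSe))
})

#' Dose-response linearity result
#'
#' @slot dppGy dose-per-pulse abscissa (Gy).
#' @slot signal measured signal (ADC or PE).
#' @slot slope,intercept OLS fit over points with dppGy <= fitMax.
#' @slot fitMax upper dose cap applied to the fit.
#' @slot deviation per-point fractional deviation (y - yhat) / yhat.
#' @export
setClass("LinearityResult",
  representation(dppGy = "numeric", signal = "numeric", slope = "numeric",
                 intercept = "numeric", fitMax = "numeric", deviation = "numeric"),
  validity = function(object) {
    if (length(object@dppGy) != length(object@signal))
      return("dpp and signal must have equal length")
    TRUE
  })

setMethod("show", "LinearityResult", function(object) {
  cat(sprintf("LinearityResult: %d points, slope %.4g per Gy, max |deviation| %.2f%%\n",
              length(object@dppGy), object@slope,
              100 * max(abs(object@deviation))))
})

## ---------------------------------------------------------------------------
## Shared accessors
## ---------------------------------------------------------------------------

#' Pixel matrix of a frame
#' @param x a \code{BeamFrame}.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname pixels
setMethod("pixels", "BeamFrame", function(x) x@pixels)

#' Acquisition metadata of a frame
#' @param x a \code{BeamFrame}.
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))
#' @rdname frameMeta
setMethod("frameMeta", "BeamFrame", function(x) x@meta)

#' Frames of a stream
#' @param x a \code{FrameStream}.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname frames
setMethod("frames", "FrameStream", function(x) x@frames)

#' Delivered-dose ledger of a stream
#' @param x a \code{FrameStream}.
#' @export
setGeneric("doseLedger", function(x) standardGeneric("doseLedger"))
#' @rdname doseLedger
setMethod("doseLedger", "FrameStream", function(x) x@ledger)

#' The 3x3 matrix of a homography
#' @param x a \code{Homography}.
#' @export
setGeneric("asMatrix", function(x) standardGeneric("asMatrix"))
#' @rdname asMatrix
setMethod("asMatrix", "Homography", function(x) x@h)

#' Plan records (sensor-coordinate lookup table)
#' @param x a \code{PlanLUT}.
#' @export
setGeneric("planRecords", function(x) standardGeneric("planRecords"))
#' @rdname planRecords
setMethod("planRecords", "PlanLUT", function(x) x@records)

#' Correction cells of a flat-field matrix
#' @param x a \code{CorrectionMatrix}.
#' @export
setGeneric("correctionCells", function(x) standardGeneric("correctionCells"))
#' @rdname correctionCells
setMethod("correctionCells", "CorrectionMatrix", function(x) x@cells)
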