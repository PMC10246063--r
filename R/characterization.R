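## Offline characterization analyses: stepper-scan spatial resolution,
## pixel re-binning, band profiles and double-Gaussian fits, profile
## residual comparison (film-style), radiation-hardness ratio-of-ratios
## trend, dose-response linearity, and the reference-scintillator signal
## comparison.

#' Spatial resolution from a position scan
#'
#' Reconstructed centroids are fit against the commanded source positions by
#' ordinary least squares; the resolution is the RMS width of the fit
#' residuals, converted to beam-plane units through the fitted slope.
#'
#' @param commandedMm commanded positions (mm), >= 3 distinct values.
#' @param centroids measured centroids (px, or mm if already transformed).
#' @return a \code{\linkS4class{ScanResult}}.
#' @export
resolutionFromScan <- function(commandedMm, centroids) {
  stopifnot(length(commandedMm) == length(centroids), length(commandedMm) >= 3)
  if (sd(commandedMm) == 0) stop("degenerate scan: all positions identical")
  fit <- lm(centroids ~ commandedMm)
  res <- residuals(fit)
  rms <- sqrt(mean(res^2))
  slope <- unname(coef(fit)[2])
  new("ScanResult", commandedMm = as.numeric(commandedMm),
      centroids = as.numeric(centroids), slope = slope,
      intercept = unname(coef(fit)[1]), residualRms = rms,
      residualRmsMm = rms / abs(slope))
}

#' Measure centroids over a simulated scan and fit the resolution
#'
#' Convenience chain: pedestal subtraction, beam finding and moment
#' measurement on every frame of a scan stream, then
#' \code{resolutionFromScan} on the x centroids.
#'
#' @param stream a scan \code{FrameStream} (frames carry commandedMm).
#' @param pedestal pedestal model.
#' @param kSigma,boxPx analysis settings.
#' @export
scanResolution <- function(stream, pedestal = NULL, kSigma = 5, boxPx = 17L) {
  cx <- vapply(stream@frames, function(fr) {
    sub <- subtractPedestal(fr, pedestal)
    region <- findBeam(sub, kSigma = kSigma)
    if (is.null(region)) return(NA_real_)
    measureBeam(sub, region, boxPx = boxPx)@centroidPx[1]
  }, numeric(1))
  cmd <- vapply(stream@frames, function(fr) fr@meta$commandedMm, numeric(1))
  ok <- !is.na(cx)
  resolutionFromScan(cmd[ok], cx[ok])
}

#' Re-bin a frame into n x n supercells
#'
#' Supercell value = sum of its member pixels, emulating coarser readout for
#' higher frame rates. Edge rows/columns that do not fill a supercell are
#' dropped and flagged in the metadata.
#'
#' @param frame a \code{BeamFrame}.
#' @param n supercell side in pixels (>= 1).
#' @return a re-binned \code{BeamFrame}; meta$rebin records n and whether a
#'   remainder was dropped.
#' @export
rebin <- function(frame, n) {
  n <- as.integer(n)
  if (n <= 0) stop("n must be a positive integer")
  px <- frame@pixels
  d <- dim(px)
  keep <- (d %/% n) * n
  dropped <- any(keep < d)
  px <- px[seq_len(keep[1]), seq_len(keep[2]), drop = FALSE]
  if (n > 1) {
    px <- rowsum(px, gl(keep[1] / n, n))          # sum row blocks
    px <- t(rowsum(t(px), gl(keep[2] / n, n)))    # sum column blocks
    dimnames(px) <- NULL
  }
  meta <- frame@meta
  meta$rebin <- list(n = n, remainderDropped = dropped)
  meta$pedestalAdc <- frame@meta$pedestalAdc * n^2
  BeamFrame(px, meta)
}

#' Band projection of an image
#'
#' Mean pixel amplitude over a band of rows (axis = "x": profile along the
#' x coordinate averaged over a band in y), the standard way to extract a
#' 1D beam profile from a 2D image.
#'
#' @param frame a \code{BeamFrame}.
#' @param axis "x" or "y": the axis the profile runs along.
#' @param bandPx band width in pixels (default 10).
#' @param centerPx 0-based center of the band on the transverse axis
#'   (default: middle of the frame).
#' @param pitchMm mm per pixel used for the returned axis (default 1:
#'   positions in px).
#' @return data.frame(x, intensity): x in 0-based pixel coordinates times
#'   \code{pitchMm}.
#' @export
bandProfile <- function(frame, axis = c("x", "y"), bandPx = 10,
                        centerPx = NULL, pitchMm = 1) {
  axis <- match.arg(axis)
  px <- frame@pixels
  d <- dim(px)
  nTrans <- if (axis == "x") d[1] else d[2]
  if (is.null(centerPx)) centerPx <- (nTrans - 1) / 2
  half <- (bandPx - 1) / 2
  lo <- .roundHalfUp(centerPx - half); hi <- lo + bandPx - 1
  if (lo < 0 || hi > nTrans - 1) stop("band extends outside the image")
  rows <- (lo:hi) + 1L
  prof <- if (axis == "x") colMeans(px[rows, , drop = FALSE])
          else rowMeans(px[, rows, drop = FALSE])
  data.frame(x = (seq_along(prof) - 1) * pitchMm, intensity = unname(prof))
}

#' Fit a double-Gaussian (core + tail) model to a 1D profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' A_n exp(-(x-c)^2/2 sigma_n^2) + A_w exp(-(x-c)^2/2 sigma_w^2).
#' Initialization: center at the profile argmax, sigma_n from FWHM/2.355,
#' A_w at 10\% of the peak with sigma_w = 10 sigma_n; the tail is
#' parameterized as sigma_w = sigma_n + delta with delta bounded positive,
#' so the wide component cannot collapse onto the core.
#'
#' @param x axis positions (mm).
#' @param y intensities.
#' @return list(profile = \code{DoubleGaussianProfile}, rmsPctPeak =
#'   residual RMS as \% of the fitted peak, converged, fit = the nlsLM
#'   object). Non-convergence is flagged, not an error.
#' @export
fitDoubleGaussian <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  peak <- max(y)
  c0 <- x[which.max(y)]
  above <- x[y >= peak / 2]
  fwhm <- if (length(above) > 1) diff(range(above)) else diff(range(x)) / 4
  s0 <- max(fwhm / 2.355, diff(range(x)) / length(x))
  model <- function(p)
    p["an"] * exp(-(x - p["ctr"])^2 / (2 * p["sn"]^2)) +
    p["aw"] * exp(-(x - p["ctr"])^2 / (2 * (p["sn"] + p["dw"])^2))
  start <- c(ctr = c0, an = 0.9 * peak, sn = s0, aw = 0.1 * peak, dw = 9 * s0)
  fit <- try(minpack.lm::nls.lm(
    par = start, fn = function(p) y - model(p),
    lower = c(min(x), 0, 1e-6, 0, 1e-6),
    upper = c(max(x), Inf, Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4)
    return(list(profile = NULL, rmsPctPeak = NA_real_, converged = FALSE,
                fit = if (inherits(fit, "try-error")) NULL else fit,
                message = if (inherits(fit, "try-error")) as.character(fit)
                          else fit$message))
  p <- fit$par
  prof <- DoubleGaussianProfile(center = p[["ctr"]], aN = p[["an"]],
                                sigmaN = p[["sn"]], aW = p[["aw"]],
                                sigmaW = p[["sn"]] + p[["dw"]])
  fittedPeak <- evalProfile(prof, p[["ctr"]])
  rms <- sqrt(mean(fit$fvec^2)) / fittedPeak * 100
  list(profile = prof, rmsPctPeak = rms, converged = TRUE, fit = fit)
}

#' RMS residual between two peak-normalized profiles, in % of peak
#'
#' Both profiles are divided by their own maxima (the comparison is of
#' relative amplitudes, so a pure scale difference vanishes), resampled onto
#' the overlap of their axes by linear interpolation, and the RMS of the
#' difference is reported in percent.
#'
#' @param p1,p2 data.frames with columns x and intensity.
#' @export
profileResidualRms <- function(p1, p2) {
  lo <- max(min(p1$x), min(p2$x)); hi <- min(max(p1$x), max(p2$x))
  if (lo >= hi) stop("profiles have disjoint axes")
  grid <- p1$x[p1$x >= lo & p1$x <= hi]
  y1 <- approx(p1$x, p1$intensity / max(p1$intensity), xout = grid)$y
  y2 <- approx(p2$x, p2$intensity / max(p2$intensity), xout = grid)$y
  sqrt(mean((y1 - y2)^2)) * 100
}

#' Radiation-hardness trend from signal and control amplitude series
#'
#' The ratio of ratios R(t) = (A_s(t)/A_s(0)) / (A_con(t)/A_con(0)) cancels
#' any drift common to the two regions (beam-current variation); its OLS
#' slope against cumulative dose is the degradation rate.
#'
#' @param timeS times from the start of irradiation (s).
#' @param doseKGy cumulative dose at each point (kGy).
#' @param As mean ADC amplitude in the beam-core signal region.
#' @param Acon mean ADC amplitude in the low-dose control region.
#' @return a \code{\linkS4class{HardnessResult}}; slopePerKGy is a fraction
#'   per kGy (multiply by 100 for \%/kGy).
#' @export
hardnessAnalysis <- function(timeS, doseKGy, As, Acon) {
  stopifnot(length(doseKGy) == length(As), length(As) == length(Acon))
  if (As[1] == 0 || Acon[1] == 0 || any(Acon == 0))
    stop("zero amplitude in a normalization denominator")
  R <- (As / As[1]) / (Acon / Acon[1])
  fit <- lm(R ~ doseKGy)
  # suppress the "essentially perfect fit" note on noise-free series
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  new("HardnessResult", timeS = as.numeric(timeS), doseKGy = as.numeric(doseKGy),
      As = as.numeric(As), Acon = as.numeric(Acon), R = R,
      slopePerKGy = unname(coef(fit)[2]), slopeSe = se)
}

#' Hardness trend from a simulated pulse-train stream
#'
#' Region definitions follow the measurement convention: the signal region
#' is the disc of radius FW3QM/2 around the beam centroid of the first
#' frame; the control region is a same-area disc at a configurable offset,
#' far enough out to receive a negligible dose. Region means use straight
#' pedestal subtraction without clamping (clamping would bias the low-
#' amplitude control mean).
#'
#' @param stream a pulse-train \code{FrameStream} with a dose ledger.
#' @param pedestal pedestal model (matrix or scalar).
#' @param controlOffsetPx c(dx, dy) offset of the control-region center from
#'   the beam centroid, in pixels.
#' @return a \code{HardnessResult}.
#' @export
hardnessFromStream <- function(stream, pedestal = NULL, controlOffsetPx) {
  stopifnot(length(stream@frames) >= 3, nrow(stream@ledger) > 0)
  f1 <- subtractPedestal(stream@frames[[1]], pedestal, clamp = TRUE)
  region <- findBeam(f1)
  if (is.null(region)) stop("no beam found in the first frame")
  m <- measureBeam(f1, region, refine = FALSE)
  prof <- bandProfile(f1, axis = "x", bandPx = 5, centerPx = m@centroidPx[2])
  radius <- fw3qm(prof$x, prof$intensity) / 2
  d <- dim(f1@pixels)
  X <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  Y <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  sigMask <- (X - m@centroidPx[1])^2 + (Y - m@centroidPx[2])^2 <= radius^2
  conMask <- (X - m@centroidPx[1] - controlOffsetPx[1])^2 +
             (Y - m@centroidPx[2] - controlOffsetPx[2])^2 <= radius^2
  if (!any(conMask)) stop("control region falls outside the frame")
  ped <- if (is.null(pedestal)) stream@frames[[1]]@meta$pedestalAdc else pedestal
  amps <- vapply(stream@frames, function(fr) {
    res <- fr@pixels - ped
    c(mean(res[sigMask]), mean(res[conMask]))
  }, numeric(2))
  rec <- stream@meta$recordedPulses
  if (is.null(rec)) rec <- seq_along(stream@frames)
  hardnessAnalysis(stream@ledger$timeS[rec], stream@ledger$cumulativeKGy[rec],
                   amps[1, ], amps[2, ])
}

#' Dose-response linearity with per-point deviations
#'
#' OLS of signal vs dose per pulse over points with dppGy <= fitMax (the
#' fit-range cap is configuration, defaulting to all points); each point's
#' fractional deviation from the fit line is reported.
#'
#' @param dppGy dose per pulse abscissa (Gy), >= 3 points.
#' @param signal measured signal (ADC or PE).
#' @param fitMax upper dose cap for the fit (default Inf).
#' @return a \code{\linkS4class{LinearityResult}}.
#' @export
linearityAnalysis <- function(dppGy, signal, fitMax = Inf) {
  stopifnot(length(dppGy) == length(signal), length(dppGy) >= 3)
  if (sd(dppGy) == 0) stop("degenerate abscissa")
  use <- dppGy <= fitMax
  if (sum(use) < 2) stop("fit-range cap leaves fewer than 2 points")
  fit <- lm(signal[use] ~ dppGy[use])
  yhat <- coef(fit)[1] + coef(fit)[2] * dppGy
  new("LinearityResult", dppGy = as.numeric(dppGy), signal = as.numeric(signal),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      fitMax = fitMax, deviation = as.numeric((signal - yhat) / yhat))
}

#' Thickness-normalized signal ratio between two scintillators
#'
#' Mean ADC amplitudes from the same source geometry divided by the
#' respective scintillator thicknesses, expressed as a ratio: the per-unit-
#' thickness light-yield advantage of one material over another.
#'
#' @param adcA,thicknessA mean ADC and thickness (mm) of scintillator A.
#' @param adcB,thicknessB mean ADC and thickness (mm) of scintillator B.
#' @export
thicknessNormalizedRatio <- function(adcA, thicknessA, adcB, thicknessB) {
  stopifnot(thicknessA > 0, thicknessB > 0, adcB > 0)
  (adcA / thicknessA) / (adcB / thicknessB)
}
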