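## Per-frame real-time analysis: pedestal subtraction, beam finding by
## thresholded connected components, ADC-weighted centroid / RMS widths /
## integrated signal with box refinement, treatment-plan comparison and
## interlock, and a clock-tick latency ledger.

#' Build a pedestal model from averaged beam-off dark frames
#'
#' @param darkFrames list of \code{BeamFrame}s (or a \code{FrameStream})
#'   acquired with the beam off.
#' @return per-pixel pedestal matrix (the mean of the dark frames).
#' @export
buildPedestal <- function(darkFrames) {
  if (is(darkFrames, "FrameStream")) darkFrames <- darkFrames@frames
  stopifnot(length(darkFrames) >= 1)
  Reduce(`+`, lapply(darkFrames, pixels)) / length(darkFrames)
}

#' Subtract a pedestal model from a frame
#'
#' Per-pixel subtraction with negatives clamped to 0 (symmetric noise around
#' zero would otherwise bias the weighted moments).
#'
#' @param frame a \code{BeamFrame}.
#' @param pedestal matrix of the same shape, or a scalar; default the
#'   frame's own pedestal level.
#' @param clamp clamp negatives at 0 (default TRUE).
#' @return residual \code{BeamFrame} (pedestal 0).
#' @export
subtractPedestal <- function(frame, pedestal = NULL, clamp = TRUE) {
  if (is.null(pedestal)) pedestal <- frame@meta$pedestalAdc
  if (is.matrix(pedestal) && !all(dim(pedestal) == dim(frame@pixels)))
    stop("pedestal model shape does not match the frame")
  res <- frame@pixels - pedestal
  if (clamp) res <- pmax(res, 0)
  meta <- frame@meta
  meta$pedestalAdc <- 0
  meta$pedestalSubtracted <- TRUE
  BeamFrame(res, meta)
}

#' Find the beam region by thresholded connected components
#'
#' Pixels above k sigma of the noise are grouped by 8-connectivity; the
#' component with the largest integrated ADC is returned (ties broken by the
#' smaller x, then y, of the component's peak pixel). Returns NULL when no
#' pixel passes the threshold.
#'
#' @param frame a pedestal-subtracted \code{BeamFrame}.
#' @param kSigma threshold in noise sigmas (default 5).
#' @param noiseSigma noise RMS in ADC; when NULL it is estimated robustly
#'   from the frame (MAD), valid while the beam occupies a small fraction
#'   of the pixels.
#' @return integer n x 2 matrix of (row, col) indices of the beam region,
#'   or NULL.
#' @export
findBeam <- function(frame, kSigma = 5, noiseSigma = NULL) {
  px <- frame@pixels
  if (is.null(noiseSigma)) {
    # robust noise estimate; for clamped (non-negative) residual frames the
    # 75th percentile of a clamped zero-mean Gaussian sits at 0.6745 sigma
    noiseSigma <- if (min(px) >= 0) quantile(px, 0.75, names = FALSE) / 0.6745
                  else mad(px, center = 0)
    if (noiseSigma <= 0) noiseSigma <- max(sd(px), .Machine$double.eps)
  }
  mask <- px > kSigma * noiseSigma
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask * 1L)
  labv <- as.vector(lab)
  sums <- tapply(as.vector(px)[labv > 0], labv[labv > 0], sum)
  best <- as.integer(names(sums)[sums == max(sums)])
  if (length(best) > 1) {
    # tie: smaller x then y of each component's peak pixel
    peaks <- t(vapply(best, function(b) {
      idx <- which(lab == b, arr.ind = TRUE)
      p <- idx[which.max(px[idx]), ]
      c(p[2], p[1])  # (x, y)
    }, numeric(2)))
    best <- best[order(peaks[, 1], peaks[, 2])][1]
  }
  which(lab == best, arr.ind = TRUE)
}

# ADC-weighted first and second central moments over a pixel index set;
# 0-based pixel coordinates (x = col - 1, y = row - 1)
.moments <- function(px, region) {
  w <- px[region]
  tot <- sum(w)
  if (tot <= 0) stop("zero total ADC in the beam region")
  x <- region[, 2] - 1; y <- region[, 1] - 1
  cx <- sum(w * x) / tot; cy <- sum(w * y) / tot
  sx <- sqrt(max(sum(w * (x - cx)^2) / tot, 0))
  sy <- sqrt(max(sum(w * (y - cy)^2) / tot, 0))
  list(centroid = c(cx, cy), widths = c(sx, sy), integral = tot,
       n = nrow(region))
}

# round half up (0.5 -> 1), used to center the refinement box
.roundHalfUp <- function(x) floor(x + 0.5)

#' Recompute moments within a square box around a coarse centroid
#'
#' The final beam position and widths are computed in a reduced pixel box
#' (default 17 x 17) centered on the rounded coarse centroid, which rejects
#' distant outliers. Boxes clipped at the frame edge carry an "edge" flag.
#'
#' @param frame a pedestal-subtracted \code{BeamFrame}.
#' @param coarseCentroid c(x, y) 0-based pixel coordinates.
#' @param boxPx odd box side length (default 17).
#' @param frameIndex metadata passthrough.
#' @return a \code{\linkS4class{BeamMeasurement}}.
#' @export
refineBox <- function(frame, coarseCentroid, boxPx = 17L,
                      frameIndex = NA_integer_) {
  boxPx <- as.integer(boxPx)
  if (boxPx %% 2L == 0L) stop("boxPx must be odd to preserve box parity")
  d <- dim(frame@pixels)
  cx <- .roundHalfUp(coarseCentroid[1]); cy <- .roundHalfUp(coarseCentroid[2])
  half <- (boxPx - 1L) %/% 2L
  x0 <- cx - half; x1 <- cx + half; y0 <- cy - half; y1 <- cy + half
  flags <- character()
  if (x0 < 0 || y0 < 0 || x1 > d[2] - 1 || y1 > d[1] - 1) flags <- "edge"
  x0 <- max(x0, 0); y0 <- max(y0, 0)
  x1 <- min(x1, d[2] - 1); y1 <- min(y1, d[1] - 1)
  region <- as.matrix(expand.grid(row = (y0:y1) + 1L, col = (x0:x1) + 1L))
  m <- .moments(frame@pixels, region)
  new("BeamMeasurement", centroidPx = m$centroid, centroidMm = c(NA_real_, NA_real_),
      widthsPx = m$widths, integralAdc = m$integral, nPixels = m$n,
      frameIndex = as.integer(frameIndex), valid = TRUE, flags = flags)
}

#' Measure beam centroid, RMS widths and integrated signal
#'
#' ADC-weighted mean position and second central moments over the beam
#' region, then refined: the moments are recomputed inside a square box
#' (default 17 x 17) centered on the rounded coarse centroid. The
#' integrated signal is the coarse-region ADC sum (the full beam integral),
#' while position and widths come from the refined box.
#'
#' @param frame a pedestal-subtracted \code{BeamFrame}.
#' @param region n x 2 (row, col) index matrix from \code{findBeam}.
#' @param refine apply the box refinement (default TRUE).
#' @param boxPx refinement box side (odd, default 17).
#' @param homography optional \code{Homography}; when given, the centroid is
#'   also reported in beam-plane mm via the inverse map.
#' @param frameIndex metadata passthrough.
#' @return a \code{\linkS4class{BeamMeasurement}}.
#' @export
measureBeam <- function(frame, region, refine = TRUE, boxPx = 17L,
                        homography = NULL, frameIndex = NA_integer_) {
  if (is.null(region) || nrow(region) == 0) stop("empty beam region")
  coarse <- .moments(frame@pixels, region)
  if (refine) {
    m <- refineBox(frame, coarse$centroid, boxPx, frameIndex = frameIndex)
    m@integralAdc <- coarse$integral   # full-region integrated signal
    m@nPixels <- coarse$n
  } else {
    m <- new("BeamMeasurement", centroidPx = coarse$centroid,
             centroidMm = c(NA_real_, NA_real_), widthsPx = coarse$widths,
             integralAdc = coarse$integral, nPixels = coarse$n,
             frameIndex = as.integer(frameIndex), valid = TRUE,
             flags = character())
  }
  if (!is.null(homography))
    m@centroidMm <- as.numeric(applyHomography(invertHomography(homography),
                                               m@centroidPx))
  m
}

#' Load a treatment-plan lookup table, pre-transformed to sensor coordinates
#'
#' Plan CSV columns: x_mm, y_mm, dose_Gy, dose_tol, pos_tol_mm, width_tol.
#' Positions are mapped through the homography once at load time.
#'
#' @param path plan CSV path, or a data.frame with those columns.
#' @param homography beam-plane/sensor \code{Homography}.
#' @return a \code{\linkS4class{PlanLUT}}.
#' @export
readPlanLUT <- function(path, homography) {
  tab <- if (is.data.frame(path)) path else read.csv(path)
  need <- c("x_mm", "y_mm", "dose_Gy", "dose_tol", "pos_tol_mm", "width_tol")
  if (!all(need %in% names(tab)))
    stop("plan needs columns: ", paste(need, collapse = ", "))
  px <- applyHomography(homography, cbind(tab$x_mm, tab$y_mm))
  rec <- data.frame(xMm = tab$x_mm, yMm = tab$y_mm, doseGy = tab$dose_Gy,
                    doseTol = tab$dose_tol, posTolMm = tab$pos_tol_mm,
                    widthTol = tab$width_tol, xPx = px[, 1], yPx = px[, 2])
  new("PlanLUT", records = rec, homography = homography)
}

#' Compare a beam measurement to the treatment plan and decide the interlock
#'
#' The measured dose is the integrated signal through the gain chain. The
#' nearest plan record (beam-plane distance) is the comparator: the
#' interlock triggers on |measured - planned| / planned above the dose
#' tolerance, on centroid-to-plan distance above the position tolerance
#' (including a measurement outside plan coverage), or on width deviation
#' from a reference width above the width tolerance. Every decision carries
#' the residual-dose bound: dose rate x interlock response interval, the
#' most dose that can slip through after a deviation.
#'
#' @param m a \code{\linkS4class{BeamMeasurement}} with centroidMm set.
#' @param plan a \code{\linkS4class{PlanLUT}}.
#' @param gains a \code{\linkS4class{GainChain}}.
#' @param doseRateGyPerS configured delivery dose rate (Gy/s).
#' @param responseTimeS interlock response interval (s), default 50 us.
#' @param refWidthPx optional expected RMS widths c(sx, sy) in px enabling
#'   the width check.
#' @return an \code{\linkS4class{InterlockDecision}}.
#' @export
compareToPlan <- function(m, plan, gains, doseRateGyPerS = 100,
                          responseTimeS = 50e-6, refWidthPx = NULL) {
  bound <- doseRateGyPerS * responseTimeS
  decide <- function(trig, reason)
    new("InterlockDecision", triggered = trig, reason = reason,
        frameIndex = m@frameIndex, residualDoseBoundGy = bound)
  if (!m@valid || any(is.na(m@centroidMm))) return(decide(TRUE, "no_beam"))
  rec <- plan@records
  d <- sqrt((rec$xMm - m@centroidMm[1])^2 + (rec$yMm - m@centroidMm[2])^2)
  i <- which.min(d)
  if (d[i] > rec$posTolMm[i]) return(decide(TRUE, "position"))
  measured <- adcToDose(m@integralAdc, gains)
  dev <- (measured - rec$doseGy[i]) / rec$doseGy[i]
  if (dev > rec$doseTol[i]) return(decide(TRUE, "dose_high"))
  if (dev < -rec$doseTol[i]) return(decide(TRUE, "dose_low"))
  if (!is.null(refWidthPx)) {
    wdev <- max(abs(m@widthsPx - refWidthPx) / refWidthPx)
    if (wdev > rec$widthTol[i]) return(decide(TRUE, "width"))
  }
  decide(FALSE, "none")
}

#' Run the full per-frame chain over a frame stream
#'
#' For each frame: pedestal subtraction, optional flat-field correction,
#' beam finding, moment measurement with box refinement, plan comparison.
#' The first triggered interlock halts the stream; frames after the halt are
#' not analysed but their delivered dose (from the stream's ledger, when
#' present) is accumulated as the residual dose that slipped through.
#'
#' @param stream a \code{\linkS4class{FrameStream}}.
#' @param plan a \code{PlanLUT}.
#' @param gains a \code{GainChain}.
#' @param pedestal pedestal model (matrix or scalar).
#' @param homography beam-plane/sensor map (defaults to the plan's).
#' @param correction optional \code{CorrectionMatrix}.
#' @param kSigma,boxPx,noiseSigma analysis settings.
#' @param doseRateGyPerS,responseTimeS,refWidthPx interlock settings, see
#'   \code{\link{compareToPlan}}.
#' @param latency a \code{\linkS4class{LatencyLedger}} of per-stage tick
#'   constants.
#' @return list(measurements, decisions, latency, haltedAt,
#'   residualDoseGy): haltedAt is NA when no interlock fired.
#' @export
processStream <- function(stream, plan, gains, pedestal = NULL,
                          homography = NULL, correction = NULL,
                          kSigma = 5, boxPx = 17L, noiseSigma = NULL,
                          doseRateGyPerS = 100, responseTimeS = 50e-6,
                          refWidthPx = NULL, latency = LatencyLedger()) {
  if (!length(stream@frames)) stop("empty frame stream")
  if (is.null(homography)) homography <- plan@homography
  measurements <- list(); decisions <- list()
  haltedAt <- NA_integer_
  for (i in seq_along(stream@frames)) {
    fr <- stream@frames[[i]]
    sub <- subtractPedestal(fr, pedestal)
    if (!is.null(correction)) sub <- applyCorrections(sub, correction, pedestalAdc = 0)
    region <- findBeam(sub, kSigma = kSigma, noiseSigma = noiseSigma)
    if (is.null(region)) {
      dec <- new("InterlockDecision", triggered = TRUE, reason = "no_beam",
                 frameIndex = i,
                 residualDoseBoundGy = doseRateGyPerS * responseTimeS)
      m <- NULL
    } else {
      m <- measureBeam(sub, region, boxPx = boxPx, homography = homography,
                       frameIndex = i)
      dec <- compareToPlan(m, plan, gains, doseRateGyPerS = doseRateGyPerS,
                           responseTimeS = responseTimeS,
                           refWidthPx = refWidthPx)
    }
    measurements[[i]] <- m
    decisions[[i]] <- dec
    if (dec@triggered) {
      warning(sprintf("interlock at frame %d: %s", i, dec@reason))
      haltedAt <- i
      break
    }
  }
  residual <- 0
  if (!is.na(haltedAt) && nrow(stream@ledger)) {
    rec <- stream@meta$recordedPulses
    if (is.null(rec)) rec <- seq_along(stream@frames)
    post <- stream@ledger$pulse > rec[haltedAt]
    # dose delivered within the response interval after the halt frame
    tHalt <- stream@ledger$timeS[rec[haltedAt]]
    inWindow <- post & stream@ledger$timeS <= tHalt + responseTimeS
    residual <- sum(stream@ledger$dppGy[inWindow])
  }
  list(measurements = measurements, decisions = decisions, latency = latency,
       haltedAt = haltedAt, residualDoseGy = residual)
}
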