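## Three-part calibration: flat-field correction matrix on a mm mesh,
## coordinate homography (see homography.R), and the ADC -> PE -> Gy gain
## chain, plus the differential scintillator-degradation monitor.

# beam-plane mm coordinates of every pixel center of a frame
.frameMmGrid <- function(frame, H) {
  d <- dim(frame@pixels)
  org <- frame@meta$originPx
  if (is.null(org)) org <- c(0, 0)
  hinv <- solve(if (is(H, "Homography")) H@h else H)
  U <- matrix(org[1] + seq_len(d[2]) - 1, nrow = d[1], ncol = d[2], byrow = TRUE)
  V <- matrix(org[2] + seq_len(d[1]) - 1, nrow = d[1], ncol = d[2])
  W <- hinv[3, 1] * U + hinv[3, 2] * V + hinv[3, 3]
  list(X = (hinv[1, 1] * U + hinv[1, 2] * V + hinv[1, 3]) / W,
       Y = (hinv[2, 1] * U + hinv[2, 2] * V + hinv[2, 3]) / W)
}

# bin per-pixel amplitudes into a mm mesh; returns cell means, counts and
# the cell-center coordinate vectors
.meshBin <- function(amp, mm, meshMm) {
  xr <- range(mm$X); yr <- range(mm$Y)
  xEdges <- seq(floor(xr[1] / meshMm) * meshMm, xr[2] + meshMm, by = meshMm)
  yEdges <- seq(floor(yr[1] / meshMm) * meshMm, yr[2] + meshMm, by = meshMm)
  ix <- findInterval(mm$X, xEdges, rightmost.closed = TRUE)
  iy <- findInterval(mm$Y, yEdges, rightmost.closed = TRUE)
  nx <- length(xEdges) - 1L; ny <- length(yEdges) - 1L
  cell <- (ix - 1L) * ny + iy
  sums <- tapply(as.vector(amp), cell, sum)
  cnts <- tapply(rep(1, length(cell)), cell, sum)
  means <- matrix(NA_real_, ny, nx)
  counts <- matrix(0, ny, nx)
  idx <- as.integer(names(sums))
  means[idx] <- sums / cnts
  counts[idx] <- cnts
  list(means = means, counts = counts,
       xCells = xEdges[-length(xEdges)] + meshMm / 2,
       yCells = yEdges[-length(yEdges)] + meshMm / 2)
}

#' Build a flat-field correction matrix from a flat-field exposure
#'
#' An image of a uniform luminescent calibration screen is binned into mesh
#' cells on the beam plane (the mesh is chosen much finer than the > 1 cm
#' scale of optical non-uniformities); the correction for a cell is the mean
#' pedestal-subtracted amplitude at the reference cell divided by the cell's
#' own mean. Cells only partially covered by pixels (active-area boundary)
#' are dropped rather than extrapolated.
#'
#' @param flat a \code{\linkS4class{BeamFrame}} of the flat-field screen.
#' @param homography beam-plane/sensor map.
#' @param meshMm mesh cell size (mm), default 1.
#' @param refPointMm beam-plane point defining the reference cell.
#' @param pedestalAdc pedestal to subtract (default: the frame's own).
#' @return a \code{\linkS4class{CorrectionMatrix}}.
#' @export
buildCorrectionMatrix <- function(flat, homography, meshMm = 1,
                                  refPointMm = c(0, 0), pedestalAdc = NULL) {
  if (is.null(pedestalAdc)) pedestalAdc <- flat@meta$pedestalAdc
  amp <- flat@pixels - pedestalAdc
  mm <- .frameMmGrid(flat, homography)
  b <- .meshBin(amp, mm, meshMm)
  full <- median(b$counts[b$counts > 0])
  b$means[b$counts < 0.9 * full] <- NA  # drop partially covered edge cells
  bad <- which(!is.na(b$means) & b$means <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("dead/non-positive flat-field cells at (row, col): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  rc <- c(which.min(abs(b$yCells - refPointMm[2])),
          which.min(abs(b$xCells - refPointMm[1])))
  refMean <- b$means[rc[1], rc[2]]
  if (is.na(refMean)) stop("reference point falls in a dropped edge cell")
  cells <- refMean / b$means
  cells[rc[1], rc[2]] <- 1
  new("CorrectionMatrix", cells = cells, meshMm = meshMm,
      xCellsMm = b$xCells, yCellsMm = b$yCells, refCell = as.integer(rc),
      homography = if (is(homography, "Homography")) homography else Homography(homography))
}

# bilinear interpolation of cell values at arbitrary mm points; NA cells and
# out-of-grid points fall back to the nearest valid cell
.interpCells <- function(cm, X, Y) {
  xs <- cm@xCellsMm; ys <- cm@yCellsMm
  fx <- (X - xs[1]) / cm@meshMm; fy <- (Y - ys[1]) / cm@meshMm
  dims <- dim(X)
  fx <- as.vector(fx); fy <- as.vector(fy)
  X <- as.vector(X); Y <- as.vector(Y)
  ix <- pmin(pmax(floor(fx), 0), length(xs) - 2); tx <- fx - ix
  iy <- pmin(pmax(floor(fy), 0), length(ys) - 2); ty <- fy - iy
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  c00 <- cm@cells[cbind(iy + 1, ix + 1)]
  c01 <- cm@cells[cbind(iy + 1, ix + 2)]
  c10 <- cm@cells[cbind(iy + 2, ix + 1)]
  c11 <- cm@cells[cbind(iy + 2, ix + 2)]
  val <- (1 - ty) * ((1 - tx) * c00 + tx * c01) + ty * ((1 - tx) * c10 + tx * c11)
  if (anyNA(val)) {
    # nearest valid cell
    nix <- pmin(pmax(round(fx), 0), length(xs) - 1)
    niy <- pmin(pmax(round(fy), 0), length(ys) - 1)
    near <- cm@cells[cbind(niy + 1, nix + 1)]
    valid <- which(!is.na(cm@cells), arr.ind = TRUE)
    if (anyNA(near)) {
      fill <- vapply(which(is.na(near)), function(i) {
        d2 <- (cm@yCellsMm[valid[, 1]] - Y[i])^2 + (cm@xCellsMm[valid[, 2]] - X[i])^2
        cm@cells[valid[which.min(d2), , drop = FALSE]]
      }, numeric(1))
      near[is.na(near)] <- fill
    }
    val[is.na(val)] <- near[is.na(val)]
  }
  matrix(val, nrow = dims[1])
}

#' Apply flat-field corrections to a frame
#'
#' The pedestal is subtracted first, then each pixel is multiplied by the
#' bilinear interpolation of the cell corrections at the pixel's beam-plane
#' position. Pixels in the reference cell are unchanged (correction 1).
#'
#' @param frame a \code{BeamFrame}.
#' @param cm a \code{\linkS4class{CorrectionMatrix}}.
#' @param pedestalAdc pedestal to subtract (default: the frame's own).
#' @return a pedestal-subtracted, corrected \code{BeamFrame} (numeric pixels,
#'   pedestal 0).
#' @export
applyCorrections <- function(frame, cm, pedestalAdc = NULL) {
  if (is.null(pedestalAdc)) pedestalAdc <- frame@meta$pedestalAdc
  mm <- .frameMmGrid(frame, cm@homography)
  corr <- .interpCells(cm, mm$X, mm$Y)
  out <- (frame@pixels - pedestalAdc) * corr
  meta <- frame@meta
  meta$pedestalAdc <- 0
  meta$pedestalSubtracted <- TRUE
  meta$corrected <- TRUE
  BeamFrame(out, meta)
}

#' Spatially differential scintillator degradation map
#'
#' Compares a current calibration-source image against a reference image of
#' the same screen: per-cell fractional loss = 1 - current/reference on the
#' mm mesh. The replace flag is raised when the area-weighted mean loss over
#' valid cells exceeds the threshold (default 1\% global signal loss).
#'
#' @param current,reference pedestal-subtracted \code{BeamFrame}s of the
#'   same geometry.
#' @param homography beam-plane/sensor map.
#' @param meshMm mesh size (mm).
#' @param threshold mean-loss fraction that flags replacement (default 0.01).
#' @param pedestalAdc pedestal override applied to both frames.
#' @return list(loss = per-cell matrix, meanLoss, replace, xCellsMm, yCellsMm).
#' @export
degradationMap <- function(current, reference, homography, meshMm = 1,
                           threshold = 0.01, pedestalAdc = NULL) {
  pedC <- if (is.null(pedestalAdc)) current@meta$pedestalAdc else pedestalAdc
  pedR <- if (is.null(pedestalAdc)) reference@meta$pedestalAdc else pedestalAdc
  stopifnot(all(dim(current@pixels) == dim(reference@pixels)))
  mm <- .frameMmGrid(reference, homography)
  bC <- .meshBin(current@pixels - pedC, mm, meshMm)
  bR <- .meshBin(reference@pixels - pedR, mm, meshMm)
  full <- median(bR$counts[bR$counts > 0])
  drop <- bR$counts < 0.9 * full
  bC$means[drop] <- NA; bR$means[drop] <- NA
  if (any(!is.na(bR$means) & bR$means <= 0))
    stop("reference image has non-positive cells")
  loss <- 1 - bC$means / bR$means
  meanLoss <- mean(loss, na.rm = TRUE)
  list(loss = loss, meanLoss = meanLoss, replace = meanLoss > threshold,
       xCellsMm = bR$xCells, yCellsMm = bR$yCells, threshold = threshold)
}

#' Convert integrated ADC signal to photoelectrons and to dose
#'
#' Gy = ADC / (ADC per PE) / (PE per Gy), the absolute calibration chain
#' anchored at the calibration geometry.
#'
#' @param adc integrated ADC counts (vectorized).
#' @param gc a \code{\linkS4class{GainChain}}.
#' @export
adcToDose <- function(adc, gc) adc / gc@adcPerPE / gc@pePerGy

#' @rdname adcToDose
#' @export
adcToPE <- function(adc, gc) adc / gc@adcPerPE

#' Cross-calibrate the gain chain against a known delivered dose
#'
#' Absolute calibration: a reference exposure of known dose (from an ion
#' chamber under the standard protocol) is analysed through the same
#' pedestal-subtraction / beam-finding / integration chain used online, and
#' the PE-per-Gy gain is set so that the measured integral reproduces the
#' known dose. Running the identical analysis on calibration and treatment
#' frames makes the beam-finding aperture cancel.
#'
#' @param frame a raw \code{BeamFrame} of the calibration exposure.
#' @param doseGy the independently known dose of that exposure.
#' @param adcPerPE the sensor gain (ADC per photoelectron).
#' @param pedestal,kSigma,noiseSigma analysis settings, as used online.
#' @return a \code{\linkS4class{GainChain}}.
#' @export
calibrateGains <- function(frame, doseGy, adcPerPE, pedestal = NULL,
                           kSigma = 5, noiseSigma = NULL) {
  stopifnot(doseGy > 0)
  sub <- subtractPedestal(frame, pedestal)
  region <- findBeam(sub, kSigma = kSigma, noiseSigma = noiseSigma)
  if (is.null(region)) stop("no beam found in the calibration frame")
  integral <- measureBeam(sub, region)@integralAdc
  GainChain(adcPerPE = adcPerPE, pePerGy = integral / adcPerPE / doseGy)
}

#' Write / read a correction matrix as CSV cells with a JSON header
#'
#' @param cm a \code{CorrectionMatrix}.
#' @param path CSV path; the header JSON is written next to it as
#'   \code{<path>.json}.
#' @export
writeCorrectionMatrix <- function(cm, path) {
  write.table(cm@cells, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(mesh_mm = cm@meshMm, x_cells_mm = cm@xCellsMm,
         y_cells_mm = cm@yCellsMm, ref_cell = cm@refCell,
         homography = as.vector(t(cm@homography@h))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCorrectionMatrix
#' @export
readCorrectionMatrix <- function(path) {
  cells <- as.matrix(read.csv(path, header = FALSE))
  dimnames(cells) <- NULL
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("CorrectionMatrix", cells = cells, meshMm = hdr$mesh_mm,
      xCellsMm = hdr$x_cells_mm, yCellsMm = hdr$y_cells_mm,
      refCell = as.integer(hdr$ref_cell),
      homography = Homography(matrix(hdr$homography, 3, 3, byrow = TRUE)))
}
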