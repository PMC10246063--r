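## Frame interchange (16-bit grayscale TIFF + JSON sidecar) and scenario
## configuration (YAML with schema validation).

#' Write frames as 16-bit grayscale TIFF with a JSON sidecar
#'
#' Single frames become single-page TIFFs; streams become multi-page TIFFs.
#' Everything the TIFF cannot carry (per-frame metadata, the dose ledger,
#' seeds) goes in \code{<path>.json}. The round trip is lossless for ADC
#' values up to 65535.
#'
#' @param x a \code{BeamFrame} or \code{FrameStream}.
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @export
writeFrames <- function(x, path, sidecar = TRUE) {
  if (is(x, "BeamFrame")) x <- FrameStream(list(x))
  stopifnot(is(x, "FrameStream"), length(x@frames) >= 1)
  pages <- lapply(x@frames, function(fr) {
    px <- fr@pixels
    if (any(px < 0) || any(px > 65535))
      stop("pixels outside the 16-bit range cannot be written losslessly")
    px / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    meta <- list(frames = lapply(x@frames, function(fr) fr@meta),
                 stream = x@meta)
    if (nrow(x@ledger)) meta$ledger <- x@ledger
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read frames from a 16-bit grayscale TIFF (+ sidecar)
#'
#' @param path TIFF path; \code{<path>.json} is read when present, otherwise
#'   default metadata is used with a warning.
#' @return a \code{\linkS4class{FrameStream}}.
#' @export
readFrames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 16L)
    stop("expected 16-bit grayscale TIFF, got ", bits, "-bit")
  sidecarPath <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecarPath)) {
    meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
  } else {
    warning("no JSON sidecar next to ", path, "; using default metadata")
  }
  frames <- lapply(seq_along(pages), function(i) {
    px <- round(pages[[i]] * 65535)
    if (length(dim(px)) == 3) px <- px[, , 1]
    attributes(px) <- list(dim = dim(px))  # drop TIFF tag attributes
    fm <- if (!is.null(meta)) as.list(as.data.frame(meta$frames)[i, , drop = FALSE]) else list()
    fm <- lapply(fm, function(v) if (is.list(v)) unlist(v) else v)
    BeamFrame(px, fm)
  })
  ledger <- if (!is.null(meta$ledger)) as.data.frame(meta$ledger) else data.frame()
  streamMeta <- if (!is.null(meta$stream)) meta$stream else list()
  FrameStream(frames, ledger = ledger, meta = as.list(streamMeta))
}

## ---------------------------------------------------------------------------
## Scenario configuration
## ---------------------------------------------------------------------------

.CONFIG_KEYS <- c("sensor", "beam", "homography", "vignette", "background",
                  "pulses", "scan", "active_area_mm", "n_frames", "plan",
                  "gains", "analysis")

#' Read and validate a YAML scenario configuration
#'
#' Top-level sections: sensor (width, height, adc_bits, adc_per_pe,
#' read_noise_e, pedestal_adc), beam (center_mm, a_n, sigma_n_mm, a_w,
#' sigma_w_mm, yield_pe), homography (9 numbers, row-major, mm -> px),
#' vignette (center_mm, dist_mm), background (hit_rate, hit_amp_adc),
#' pulses (dose_per_pulse_Gy, pulse_width_s, rep_rate_Hz, duration_s),
#' scan (positions_mm), active_area_mm, n_frames, plan (path), gains
#' (adc_per_pe, pe_per_Gy), analysis (free-form options). Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return the validated configuration list.
#' @export
readScenarioConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$sensor) || is.null(cfg$beam))
    stop("configuration needs at least 'sensor' and 'beam' sections")
  cfg
}

#' Build the simulator objects from a scenario configuration
#'
#' @param cfg a configuration list from \code{readScenarioConfig}.
#' @return list(sensor = \code{SensorModel}, truth = \code{SceneTruth},
#'   pulses = \code{PulseStructure} or NULL).
#' @export
sceneFromConfig <- function(cfg) {
  s <- cfg$sensor
  sensor <- SensorModel(widthPx = s$width, heightPx = s$height,
                        adcBits = s$adc_bits %||% 12L,
                        adcPerPE = s$adc_per_pe %||% 2.593,
                        readNoiseE = s$read_noise_e %||% 2.5,
                        pedestalAdc = s$pedestal_adc %||% 100,
                        roi = unlist(s$roi) %||% integer())
  b <- cfg$beam
  ctr <- unlist(b$center_mm) %||% c(0, 0)
  beamX <- DoubleGaussianProfile(center = ctr[1], aN = b$a_n %||% 1,
                                 sigmaN = b$sigma_n_mm,
                                 aW = b$a_w %||% 0,
                                 sigmaW = b$sigma_w_mm %||% (10 * b$sigma_n_mm))
  beamY <- DoubleGaussianProfile(center = ctr[2], aN = b$a_n %||% 1,
                                 sigmaN = b$sigma_n_mm,
                                 aW = b$a_w %||% 0,
                                 sigmaW = b$sigma_w_mm %||% (10 * b$sigma_n_mm))
  H <- if (!is.null(cfg$homography))
         Homography(matrix(unlist(cfg$homography), 3, 3, byrow = TRUE))
       else Homography()
  vig <- cfg$vignette
  bg <- cfg$background
  truth <- SceneTruth(beamX, beamY, yieldPE = b$yield_pe, homography = H,
                      vignetteCenterMm = unlist(vig$center_mm) %||% c(0, 0),
                      vignetteDistMm = vig$dist_mm %||% Inf,
                      bgHitRate = bg$hit_rate %||% 0,
                      bgHitAmpAdc = bg$hit_amp_adc %||% 50,
                      activeAreaMm = unlist(cfg$active_area_mm) %||% c(-50, 50, -50, 50))
  pulses <- NULL
  if (!is.null(cfg$pulses)) {
    p <- cfg$pulses
    pulses <- PulseStructure(p$dose_per_pulse_Gy, p$pulse_width_s,
                             p$rep_rate_Hz, p$duration_s)
  }
  list(sensor = sensor, truth = truth, pulses = pulses)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
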