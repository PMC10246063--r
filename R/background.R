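## Background budget calculators: bremsstrahlung signal/background per
## FLASH frame, the neutron hit estimate for proton operation, and the
## shielding-effect bookkeeping.

#' FLASH delivery specification for the frame budget
#'
#' @slot totalDoseGy therapeutic dose of the delivery (Gy).
#' @slot deliveryTimeS total delivery time (s).
#' @slot pePerGy gain of the optical chain (PE per Gy per frame).
#' @slot bkgFraction bremsstrahlung background as a fraction of the signal
#'   (default 0.009, the shielded clinical-beam measurement).
#' @slot darkNoiseE readout dark noise (electrons, default 2.3).
#' @export
setClass("FlashDeliverySpec",
  representation(totalDoseGy = "numeric", deliveryTimeS = "numeric",
                 pePerGy = "numeric", bkgFraction = "numeric",
                 darkNoiseE = "numeric"),
  validity = function(object) {
    if (object@totalDoseGy < 0) return("total dose must be >= 0")
    if (any(c(object@deliveryTimeS, object@pePerGy) <= 0))
      return("delivery time and gain must be > 0")
    TRUE
  })

#' @param totalDoseGy,deliveryTimeS,pePerGy,bkgFraction,darkNoiseE see slots.
#' @rdname FlashDeliverySpec-class
#' @export
FlashDeliverySpec <- function(totalDoseGy = 10, deliveryTimeS = 0.2,
                              pePerGy = 1080 / 0.17, bkgFraction = 0.009,
                              darkNoiseE = 2.3) {
  new("FlashDeliverySpec", totalDoseGy = as.numeric(totalDoseGy),
      deliveryTimeS = as.numeric(deliveryTimeS), pePerGy = as.numeric(pePerGy),
      bkgFraction = as.numeric(bkgFraction), darkNoiseE = as.numeric(darkNoiseE))
}

#' Per-frame signal and bremsstrahlung background across pulse rates
#'
#' For each pulse rate the total dose is split over rate x delivery-time
#' pulses (one triggered frame each): DPP = total / n, signal PE =
#' gain x DPP (nearest PE), background = background fraction x signal
#' (nearest PE), and the last column compares the background to the dark
#' noise. The same dose spread over more pulses gives proportionally
#' smaller per-frame background.
#'
#' @param spec a \code{\linkS4class{FlashDeliverySpec}}.
#' @param pulseRatesHz pulse rates to tabulate (default the 100-1000 Hz
#'   clinical range).
#' @return data.frame: pulseRateHz, nPulses, dppGy, signalPE, bkgPE,
#'   bkgOverDark.
#' @export
flashFrameBudget <- function(spec, pulseRatesHz = c(100, 200, 500, 800, 1000)) {
  n <- pulseRatesHz * spec@deliveryTimeS
  if (any(n < 1)) stop("pulse rate x delivery time must give at least one pulse")
  dpp <- spec@totalDoseGy / n
  signal <- round(spec@pePerGy * dpp)
  bkg <- round(spec@bkgFraction * signal)
  data.frame(pulseRateHz = pulseRatesHz, nPulses = n, dppGy = dpp,
             signalPE = signal, bkgPE = bkg,
             bkgOverDark = round(bkg / spec@darkNoiseE, 1))
}

#' Neutron environment for proton-beam background estimation
#'
#' @slot fluencePerProtonCm2 neutron fluence per incident proton (cm^-2).
#' @slot sensorAreaCm2 camera sensor area (cm^2).
#' @slot beamCurrentNA proton beam current (nA).
#' @slot frameTimeS frame time (s).
#' @slot sensorThicknessCm silicon sensor thickness (cm).
#' @slot crossSectionBarn mean neutron-silicon total cross section (barn).
#' @slot numberDensityCm3 silicon number density (cm^-3).
#' @export
setClass("NeutronEnvironment",
  representation(fluencePerProtonCm2 = "numeric", sensorAreaCm2 = "numeric",
                 beamCurrentNA = "numeric", frameTimeS = "numeric",
                 sensorThicknessCm = "numeric", crossSectionBarn = "numeric",
                 numberDensityCm3 = "numeric"),
  validity = function(object) {
    v <- c(object@fluencePerProtonCm2, object@sensorAreaCm2, object@frameTimeS,
           object@sensorThicknessCm, object@crossSectionBarn,
           object@numberDensityCm3)
    if (any(v <= 0)) return("all environment fields except the current must be > 0")
    if (object@beamCurrentNA < 0) return("beam current must be >= 0")
    TRUE
  })

#' @param fluencePerProtonCm2,sensorAreaCm2,beamCurrentNA,frameTimeS see slots.
#' @param sensorThicknessCm,crossSectionBarn,numberDensityCm3 see slots.
#' @rdname NeutronEnvironment-class
#' @export
NeutronEnvironment <- function(fluencePerProtonCm2 = 3e-5, sensorAreaCm2 = 0.07,
                               beamCurrentNA = 800, frameTimeS = 50e-6,
                               sensorThicknessCm = 0.075,
                               crossSectionBarn = 1.2,
                               numberDensityCm3 = 5e22) {
  new("NeutronEnvironment", fluencePerProtonCm2 = as.numeric(fluencePerProtonCm2),
      sensorAreaCm2 = as.numeric(sensorAreaCm2),
      beamCurrentNA = as.numeric(beamCurrentNA),
      frameTimeS = as.numeric(frameTimeS),
      sensorThicknessCm = as.numeric(sensorThicknessCm),
      crossSectionBarn = as.numeric(crossSectionBarn),
      numberDensityCm3 = as.numeric(numberDensityCm3))
}

.BARN_CM2 <- 1e-24

#' Neutron hit budget per frame for proton operation
#'
#' N_n = fluence-per-proton x sensor area x protons per frame, with protons
#' per frame = I / e x frame time. The interacting fraction is Q = tau /
#' lambda with interaction length lambda = 1 / (sigma eta) (barn converted
#' to cm^2); hits per frame = N_n x Q.
#'
#' @param env a \code{\linkS4class{NeutronEnvironment}}.
#' @return list(protonsPerFrame, neutronsPerFrame, interactionFractionQ,
#'   hitsPerFrame).
#' @export
neutronHits <- function(env) {
  protons <- env@beamCurrentNA * 1e-9 / .ELEMENTARY_CHARGE_C * env@frameTimeS
  Nn <- env@fluencePerProtonCm2 * env@sensorAreaCm2 * protons
  lambda <- 1 / (env@crossSectionBarn * .BARN_CM2 * env@numberDensityCm3)
  Q <- env@sensorThicknessCm / lambda
  list(protonsPerFrame = protons, neutronsPerFrame = Nn,
       interactionFractionQ = Q, hitsPerFrame = Nn * Q)
}

#' Shielding-effect summary from paired background/signal measurements
#'
#' For each beam energy, the background-to-signal ADC percentage with and
#' without the radiation shield, the per-energy reduction factor
#' (unshielded \% / shielded \%), and their mean. Percentages are rounded to
#' one decimal before the factors, mirroring the tabulation convention;
#' published percentages can be supplied directly via pct columns.
#'
#' @param records data.frame with columns energyMeV, shielded (logical),
#'   bkgAdc, signalAdc, and optionally pct (percent, overrides the computed
#'   value).
#' @return list(table = per-energy data.frame with unshieldedPct,
#'   shieldedPct and factor, meanFactor).
#' @export
shieldSummary <- function(records) {
  need <- c("energyMeV", "shielded", "bkgAdc", "signalAdc")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  # round half away from zero (tabulation convention), guarding against
  # binary-representation artifacts like 2.3/0.4 = 5.74999...
  round1 <- function(x) round(x + 1e-9, 1)
  pct <- if ("pct" %in% names(records) ) records$pct else rep(NA_real_, nrow(records))
  computed <- round1(100 * records$bkgAdc / records$signalAdc)
  pct <- ifelse(is.na(pct), computed, pct)
  energies <- sort(unique(records$energyMeV))
  rows <- lapply(energies, function(e) {
    sel <- records$energyMeV == e
    iu <- which(sel & !records$shielded); is <- which(sel & records$shielded)
    if (length(iu) != 1 || length(is) != 1)
      stop("each energy needs exactly one shielded and one unshielded record")
    data.frame(energyMeV = e, unshieldedPct = pct[iu], shieldedPct = pct[is],
               factor = round1(pct[iu] / pct[is]))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, meanFactor = mean(tab$factor))
}
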