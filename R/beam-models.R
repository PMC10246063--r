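## Analytic beam-profile and dosimetry models shared by the simulator and the
## offline analyses.

# physical constants
.ELEMENTARY_CHARGE_C <- 1.602176634e-19
.MEV_TO_J <- 1.602176634e-13

#' Evaluate a double-Gaussian beam profile
#'
#' Computes A_n exp(-(x-c)^2 / (2 sigma_n^2)) + A_w exp(-(x-c)^2 / (2 sigma_w^2)).
#'
#' @param profile a \code{\linkS4class{DoubleGaussianProfile}}.
#' @param x positions (mm), vectorized.
#' @return intensity at \code{x} (unitless).
#' @export
evalProfile <- function(profile, x) {
  d2 <- (x - profile@center)^2
  profile@aN * exp(-d2 / (2 * profile@sigmaN^2)) +
    profile@aW * exp(-d2 / (2 * profile@sigmaW^2))
}

#' Unit-normalized profile density
#'
#' \code{evalProfile} divided by its integral
#' sqrt(2 pi) (A_n sigma_n + A_w sigma_w), so it integrates to 1.
#'
#' @inheritParams evalProfile
#' @export
profileDensity <- function(profile, x)
  evalProfile(profile, x) / profileIntegral(profile)

#' Analytic integral of a double-Gaussian profile over the whole axis
#' @param profile a \code{DoubleGaussianProfile}.
#' @export
profileIntegral <- function(profile)
  sqrt(2 * pi) * (profile@aN * profile@sigmaN + profile@aW * profile@sigmaW)

#' Full width at three-quarters maximum of a sampled profile
#'
#' The beam-core width used for dose-per-pulse normalization: the distance
#' between the outermost axis positions where the intensity first crosses
#' 3/4 of the peak on each side, with linear interpolation between the
#' bracketing samples. For a pure Gaussian the closed form is
#' 2 sigma sqrt(2 ln(4/3)) = 1.51699 sigma.
#'
#' @param x axis positions (mm), strictly increasing.
#' @param intensity sampled intensities; must have a unique maximum above
#'   the baseline.
#' @return width in the units of \code{x}.
#' @export
fw3qm <- function(x, intensity) {
  stopifnot(length(x) == length(intensity), length(x) >= 3)
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  peak <- max(intensity)
  if (!(peak > 0) || all(intensity == intensity[1]))
    stop("no peak: profile is flat or non-positive")
  thr <- 0.75 * peak
  above <- intensity >= thr
  if (!any(above)) stop("no samples reach 3/4 of the peak")
  # outermost crossings: scan inward from each end
  iL <- which(above)[1]
  iR <- tail(which(above), 1)
  xL <- if (iL == 1) x[1] else {
    f <- (thr - intensity[iL - 1]) / (intensity[iL] - intensity[iL - 1])
    x[iL - 1] + f * (x[iL] - x[iL - 1])
  }
  xR <- if (iR == length(x)) x[length(x)] else {
    f <- (thr - intensity[iR + 1]) / (intensity[iR] - intensity[iR + 1])
    x[iR + 1] + f * (x[iR] - x[iR + 1])
  }
  xR - xL
}

#' Dose per pulse from charge fluence and stopping power
#'
#' DPP = phi * dE/dx: the charge fluence (nC/cm^2) is converted to particle
#' fluence via the elementary charge, multiplied by the mass stopping power
#' (MeV cm^2/g), and the energy deposition converted MeV/g -> Gy.
#'
#' @param fd a \code{\linkS4class{FluenceDose}}.
#' @return dose per pulse in Gy.
#' @examples
#' # 4.0 nC/cm^2 of 8 MeV electrons in water (~2.0 MeV cm^2/g) -> 8.0 Gy
#' dosePerPulse(FluenceDose(4.0, 2.0))
#' @export
dosePerPulse <- function(fd) {
  particles_per_cm2 <- fd@fluenceNCcm2 * 1e-9 / .ELEMENTARY_CHARGE_C
  mev_per_g <- particles_per_cm2 * fd@stoppingPower
  mev_per_g * .MEV_TO_J * 1000  # J/kg = Gy
}

#' Average, instantaneous and cumulative dose rates of a pulse train
#'
#' avg = DPP x f_rep; instantaneous = DPP / pulse width;
#' cumulative = avg x duration.
#'
#' @param ps a \code{\linkS4class{PulseStructure}}.
#' @return list with avgGyPerS, instGyPerS, cumulativeGy.
#' @export
doseRates <- function(ps) {
  if (ps@dppGy == 0)
    return(list(avgGyPerS = 0, instGyPerS = 0, cumulativeGy = 0))
  if (ps@pulseWidthS == 0)
    stop("instantaneous dose rate undefined: pulse width is 0 with DPP > 0")
  avg <- ps@dppGy * ps@repRateHz
  list(avgGyPerS = avg,
       instGyPerS = ps@dppGy / ps@pulseWidthS,
       cumulativeGy = avg * ps@durationS)
}

#' Birks-quenched scintillation light yield per unit path length
#'
#' dL/dx = S dE/dx / (1 + kB dE/dx): light output saturates at high linear
#' energy transfer. kB = 0 recovers the unquenched linear response.
#'
#' @param dEdx linear energy transfer (MeV/cm), vectorized, >= 0.
#' @param bp a \code{\linkS4class{BirksParams}}.
#' @export
birksYield <- function(dEdx, bp) {
  stopifnot(all(dEdx >= 0))
  bp@S * dEdx / (1 + bp@kB * dEdx)
}

## ---------------------------------------------------------------------------
## Stopping-power lookup
## ---------------------------------------------------------------------------

# Approximate mass stopping powers of water (MeV cm^2/g), ESTAR/PSTAR scale.
# The 8 MeV electron entry is the effective value the dosimetry chain uses.
.DEFAULT_STOPPING_POWER <- data.frame(
  particle = c(rep("electron", 6), rep("proton", 3)),
  energy_MeV = c(6, 8, 9, 12, 16, 100, 170, 200, 240),
  stopping_power_MeVcm2_per_g = c(1.94, 2.00, 2.02, 2.05, 2.10, 2.20,
                                  5.00, 4.49, 3.94),
  stringsAsFactors = FALSE)

#' Mass stopping power of water for a particle and energy
#'
#' Linear interpolation in an embedded ESTAR/PSTAR-scale table (electrons at
#' 6-100 MeV, protons at 170-240 MeV); values are approximate and can be
#' overridden with \code{loadStoppingPowerTable}. Energies outside the table
#' range are an error rather than an extrapolation.
#'
#' @param particle "electron" or "proton".
#' @param energyMeV kinetic energy (MeV).
#' @param table override table, as returned by \code{loadStoppingPowerTable}.
#' @return stopping power in MeV cm^2/g.
#' @export
stoppingPower <- function(particle, energyMeV, table = .DEFAULT_STOPPING_POWER) {
  rows <- table[table$particle == particle, ]
  if (!nrow(rows)) stop("no stopping-power entries for particle: ", particle)
  rng <- range(rows$energy_MeV)
  if (energyMeV < rng[1] || energyMeV > rng[2])
    stop(sprintf("energy %.3g MeV outside tabulated range [%g, %g] for %s",
                 energyMeV, rng[1], rng[2], particle))
  approx(rows$energy_MeV, rows$stopping_power_MeVcm2_per_g,
         xout = energyMeV)$y
}

#' Read a stopping-power override table from CSV
#'
#' Expected columns: particle, energy_MeV, stopping_power_MeVcm2_per_g.
#'
#' @param path CSV file path.
#' @export
loadStoppingPowerTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("particle", "energy_MeV", "stopping_power_MeVcm2_per_g")
  if (!all(need %in% names(tab)))
    stop("stopping-power table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$stopping_power_MeVcm2_per_g <= 0))
    stop("stopping powers must be > 0")
  tab
}

#' Sample a profile to a CSV file / read it back
#'
#' Profiles are interchanged as two-column CSV (x_mm, intensity).
#'
#' @param profile a \code{DoubleGaussianProfile}.
#' @param x sample positions (mm).
#' @param path output CSV path.
#' @export
writeProfileCsv <- function(profile, x, path) {
  write.csv(data.frame(x_mm = x, intensity = evalProfile(profile, x)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileCsv
#' @return \code{readProfileCsv}: data.frame with x_mm and intensity.
#' @export
readProfileCsv <- function(path) {
  tab <- read.csv(path)
  if (!all(c("x_mm", "intensity") %in% names(tab)))
    stop("profile CSV needs columns x_mm, intensity")
  tab
}
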