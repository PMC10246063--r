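---
title: "Methods: simulating and analysing a scintillator camera beam monitor"
author: "scintbeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a scintillator camera beam monitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The monitoring problem

FLASH radiotherapy delivers a full therapeutic dose at time-averaged rates
above 40 Gy/s — three orders of magnitude beyond conventional treatment. At
those rates a delivery fault can deposit a harmful dose in milliseconds, so
regulation (IEC 60601-2-1) caps the dose delivered *after* an interlock is
asserted at 10% of the prescription. A monitor for such beams must image the
beam in 2D, measure position, width and dose every frame, compare them to
the treatment plan, and assert an interlock within tens of microseconds.

One practical architecture is a thin transmissive scintillator sheet viewed
obliquely by a fast CMOS camera: the beam deposits energy in the sheet, the
camera integrates the scintillation light into frames, and per-frame image
analysis produces the beam parameters. `scintbeam` implements the full
computational stack of such a monitor — a frame simulator that serves as
ground truth, the calibration chain, the per-frame real-time analysis with
plan comparison, and the offline characterization analyses — so every
algorithm can be validated against known inputs before it ever sees a real
camera.

## Data model and conventions

Pixels are 0-based with pixel centers at integer coordinates; `pixels(frame)`
is indexed `[row, col]` with `x = col - 1`, `y = row - 1`. The beam plane is
measured in mm with its origin at the scintillator center. A single 3×3
projective matrix (`Homography`, stored with `h[3,3] = 1`) maps beam-plane mm
to sensor pixels; the oblique (~40°) camera view makes this genuinely
projective, not affine. All modules share these conventions.

Two sensor presets bracket the use cases: `camESensor()` (~2 MP, 12-bit,
2.5 e⁻ read noise, gain 2.593 ADC per photoelectron from the
2800 ADC ↔ 1080 PE peak-signal correspondence) for pulsed electron beams,
and `camPSensor()` (1 MP read through a 212×212 ROI ≈ 45k pixels, 15 e⁻)
for continuous proton beams at 20 kHz frame rates. The published sources
give only approximate pixel counts ("nearly 2 MP", "1 MP"), so the exact
dimensions here are stand-ins; nothing downstream depends on them.

## The frame simulator

`renderFrame()` composes the physics the analyses must cope with:

* **Beam shape.** Each axis is a double Gaussian
  $f(x) = A_n e^{-(x-c)^2/2\sigma_n^2} + A_w e^{-(x-c)^2/2\sigma_w^2}$,
  a narrow primary core plus a wide low-amplitude tail — the shape that fits
  measured clinical electron-beam profiles. The 2D beam is the separable
  product, normalized to unit integral and scaled by the total
  photoelectron yield per frame.
* **Projection.** The expected signal at a pixel is evaluated by *inverse*
  mapping (sensor pixel → beam plane) with the absolute Jacobian determinant
  of that map as the density weight, so total signal is conserved under any
  projective distortion. No anti-aliasing beyond per-pixel evaluation: mesh
  effects are negligible once the spot spans a few pixels.
* **Vignetting.** The dominant flat-field non-uniformity is the geometric
  $1/r^2$ dependence on the optical path from scintillator point to lens.
  With the lens at standoff $d$ over a reference point, a point at in-plane
  offset $\rho$ receives the factor $d^2/(d^2+\rho^2)$ — exactly 1 at the
  reference point.
* **Noise.** Pixel value = pedestal + round(gain × (Poisson(expected PE) +
  Gaussian read noise)), clipped to the ADC range. If more than 1% of pixels
  sit at the ceiling the frame carries a saturation flag.
* **Background hits.** Stray photons (bremsstrahlung on the sensor) appear
  as sparse single-pixel impulses: a Poisson number of hits per frame with
  an exponential amplitude spectrum. The published data constrain the
  occupancy, not the amplitudes, so the exponential is a modelling choice
  with configurable parameters.

Rendering is pure: a seed plus identical inputs gives a bit-identical frame.

`simulateScan()` translates the beam center in beam-plane mm before
projection, emulating a stepper-driven source; `simulatePulseTrain()`
emulates extended irradiation with per-pulse Gaussian yield fluctuations and
radiation damage (below), and keeps a per-pulse delivered-dose ledger.

### What the simulator does not emulate

Lens point-spread and astigmatism, scintillator afterglow, ambient-light
leaks, fixed-pattern sensor noise, energy-loss straggling in the sheet, and
the chemistry of radiochromic film. Tests passing on simulated frames
therefore validate the *algorithms* (estimator correctness, bias, noise
scaling, interlock logic), not the hardware; the film comparison is
represented abstractly as profile-versus-profile residuals.

## Dosimetry models

Dose per pulse is $\mathrm{DPP} = \phi \cdot dE/dx$: the pulse's charge
fluence $\phi$ (nC/cm², measured with a Faraday cup and referred to the beam
core enclosed by the full width at three-quarters maximum, FW3QM), divided
by the elementary charge to get particles/cm², times the mass stopping power
of water (MeV·cm²/g), converted to Gy. An embedded stopping-power table
(electrons 6–100 MeV, protons 170–240 MeV in water; approximate
ESTAR/PSTAR-scale values, with 2.0 MeV·cm²/g at 8 MeV as the value the dose
chain uses) is linearly interpolated and can be overridden from CSV.
Derived rates: average $\langle dD/dt\rangle = \mathrm{DPP}\cdot f_{rep}$,
instantaneous $D_{ins} = \mathrm{DPP}/\delta t_{pulse}$, cumulative
$\langle dD/dt\rangle \cdot t$. Scintillator saturation at high linear
energy transfer follows the Birks relation
$dL/dx = S\,(dE/dx)/(1 + k_B\, dE/dx)$.

The FW3QM of a sampled profile is the distance between the outermost
crossings of ¾ of the peak, linearly interpolated between bracketing
samples; for a Gaussian the closed form is $2\sigma\sqrt{2\ln(4/3)} =
1.517\sigma$, which the implementation matches to the sampling step.

## Calibration

**Flat-field matrix.** An image of a uniform luminescent screen is binned on
a 1 mm mesh over the beam plane (much finer than the >1 cm scale of optical
non-uniformities); each cell's correction is the reference-cell mean over
the cell mean. Edge cells only partially covered by pixels are dropped, not
extrapolated — they are unconstrained. Application is per-pixel bilinear
interpolation between cell centers (the interpolation order is not fixed by
the source material; bilinear is the minimal smooth choice), after pedestal
subtraction. The flattening criterion is evaluated at the cell scale:
per-pixel shot noise is irreducible and not the correction's job.

**Homography.** Estimated from ≥4 point correspondences by the normalized
direct linear transform: Hartley normalization (centroid to origin, mean
distance √2) of both point sets, SVD of the 2n×9 design matrix, and
un-normalization, stored with $h_{33}=1$. Noise-free correspondences are
recovered to numerical precision; the reprojection RMS is kept on the
object. Degenerate configurations (collinear points) are detected through
the singular-value spectrum and rejected. Following the operational design
argument, images are never transformed during treatment: the *plan* is
transformed once into sensor coordinates at load time.

**Gain chain.** Gy = ADC / (ADC per PE) / (PE per Gy). The ADC→PE gain is a
sensor property; PE per Gy is set by cross-calibration: a reference
exposure of independently known dose (ion-chamber protocol) is analysed
through *the same* pedestal-subtraction / beam-finding / integration chain
used online (`calibrateGains()`), so the beam-finding aperture cancels
between calibration and treatment frames.

**Degradation monitor.** Periodic images of a stable external source are
compared cell-by-cell to a reference image: loss = 1 − current/reference.
The replacement flag is raised when the area-weighted mean loss exceeds 1%
(configurable), matching the stated replacement policy.

## Real-time per-frame analysis

The chain mirrors what fits in FPGA firmware:

1. **Pedestal subtraction** against a model averaged from beam-off dark
   frames; negatives are clamped at zero. The clamp avoids moment bias from
   symmetric noise at the cost of a small positive floor — the robust noise
   estimator used downstream accounts for the clamped distribution (the
   75th percentile of clamped zero-mean Gaussian noise sits at 0.6745 σ).
2. **Beam finding**: pixels above k·σ of the noise (k = 5 by default — the
   source material does not state a threshold; 5σ keeps the false-positive
   rate per ~10⁴-pixel frame well under 1%) are grouped by 8-connectivity
   (`EBImage::bwlabel`); the largest-integral component wins, ties broken
   by the smaller x then y of the peak pixel.
3. **Moments**: ADC-weighted centroid and second central moments, then
   refined inside a square box (17×17 by default, odd sizes only) centered
   on the coarse centroid rounded half-up. The box rejects distant
   outliers; boxes clipped at the frame edge carry an `"edge"` flag. The
   integrated signal is the full coarse-region sum. The box must cover the
   spot to ±2.5σ or more; for wide spots pass a larger `boxPx`, since an
   aperture at ~1σ visibly biases centroids.
4. **Plan comparison**: nearest plan record in beam-plane distance (when
   several records could apply, nearest-record comparison is the rule);
   interlock on fractional dose deviation beyond tolerance (default 10%),
   position error beyond tolerance, or width deviation from a reference.
   Every decision carries the residual-dose bound $R \times dT_i$ — dose
   rate times the interlock response interval — the most dose that can
   slip through after a deviation (0.005 Gy at 100 Gy/s and 50 µs).
5. **Latency ledger**: per-stage durations in 4 ns clock ticks are
   configuration constants (frame 12500 ticks = 50 µs; transfer 10700;
   beam finding 68; position 76; widths 47; total processing 10891 ticks =
   43.6 µs). Latency is modelled, never measured: the package makes no
   wall-clock claims.

`processStream()` halts at the first triggered interlock; pulses delivered
within the response interval after the halt are summed from the dose ledger
as the realized residual dose.

## Characterization analyses

* **Scan resolution**: centroids vs commanded positions, ordinary least
  squares; the resolution is the residual RMS converted to beam-plane units
  through the fitted slope. On real benches this number is dominated by an
  extrinsic floor (source positioning and emission stability), which is why
  re-binning pixels 2×2 barely degrades it while the spot shares charge
  over many pixels — the tests emulate exactly that regime.
* **Re-binning** sums n×n supercells (dropping and flagging remainders),
  conserving total ADC.
* **Band profiles** average a 10-pixel band through the beam center;
  `fitDoubleGaussian()` fits the core+tail model by Levenberg–Marquardt
  (`minpack.lm::nls.lm`; the tail is parameterized as
  $\sigma_w = \sigma_n + \delta$, $\delta > 0$, so it cannot collapse onto
  the core). Initialization: center at the argmax, $\sigma_n$ from
  FWHM/2.355, tail at 10% of the peak with $\sigma_w = 10\sigma_n$.
  Profile-vs-profile agreement is reported as the RMS of the difference of
  peak-normalized curves, in percent of peak.
* **Radiation hardness**: the ratio of ratios
  $R(t) = \dfrac{A_s(t)/A_s(0)}{A_{con}(t)/A_{con}(0)}$
  between a beam-core signal region and a low-dose control region cancels
  any drift common to both (beam-current variation cancels exactly); the
  degradation rate is the OLS slope of $R$ against cumulative dose. The
  signal region is the FW3QM disc of the first frame; the control region is
  a same-area disc at a configurable offset, far enough out that its local
  dose is a few tenths of a percent of the core's. Region means use
  unclamped pedestal subtraction — clamping would bias the low-amplitude
  control mean.
* **Linearity**: OLS of signal vs dose per pulse below a configurable cap
  (by default all points are fit; excluding a suspect high point is a
  configuration, not a hard-coded rule), with per-point fractional
  deviations from the fit line.

### The degradation model and why it is spatial

A uniform (whole-frame) yield loss would cancel exactly in $R$ — the
statistic is built to be blind to it. Physically, damage follows the local
dose: the simulator therefore degrades each pixel by
$1 - \text{rate} \times \text{cumulative dose} \times f(x,y)$, where
$f$ is the beam density normalized to its *mean over the FW3QM disc*. The
core-mean normalization matters: the nominal dose per pulse is defined from
the charge enclosed by the FW3QM over the core area, i.e. it is a
core-average dose, and normalizing to the peak instead would make the
simulated core degrade ~15% slower than the nominal rate. With this model
the package's hardness analysis recovers an injected −0.025 %/kGy over the
full 216 kGy schedule (27 000 pulses of 8 Gy at 30 Hz, 1.6% pulse noise) to
better than 1%.

## Background budgets

* **Bremsstrahlung per FLASH frame**: a total dose split over
  rate × delivery-time pulses (the tabulated benchmark is 10 Gy over 0.2 s;
  the delivery time, not the quoted average rate, is what reproduces the
  published table) gives per-frame signal PE through the gain chain;
  background is a fixed fraction of signal (0.9%, the shielded
  clinical-beam measurement), rounded to the nearest PE before the
  background/dark-noise ratio. Backgrounds fall inversely with pulse rate
  because the same dose spreads over more frames.
* **Neutrons in proton mode**: $N_n = \phi\, A_{sens}\, (I_p/e)\,\delta t$
  neutrons per frame; the interacting fraction is $Q = \tau/\lambda$ with
  $\lambda = 1/(\sigma\eta)$, 1 barn = 10⁻²⁴ cm². With the published
  constants Q is 0.45% (printing as 0.4%) and the 30–800 nA current range
  spans ~0.1–2.4 hits/frame.
* **Shield bookkeeping**: background/signal percentages rounded to one
  decimal before per-energy reduction factors, mirroring the tabulation
  convention; published percentages can be supplied directly when the
  printed table's own rounding is not reproducible from its ADC columns.

## Numerical choices and degenerate inputs

The printed functional form of the double Gaussian in the source material
omits the minus sign and is ambiguous between $x^2/(2\sigma^2)$ and
$(x/(2\sigma))^2$; only the standard Gaussian $e^{-x^2/2\sigma^2}$ is
normalizable and consistent with the reported widths, so that is what is
implemented. The elementary charge is fixed at 1.602176634 × 10⁻¹⁹ C and
MeV→J at 1.602176634 × 10⁻¹³. Flat or all-zero profiles are a no-peak
error in `fw3qm()`; a zero pulse width with nonzero DPP is an undefined
instantaneous rate; dead flat-field cells, degenerate homography
configurations, zero normalization denominators and empty streams all raise
informative errors rather than propagating NaN. Rounding that mirrors
printed tables adds 10⁻⁹ before `round()` to avoid binary-representation
artifacts (2.3/0.4 = 5.7499…).

## Problem sizes

The test and acceptance runs use desk-scale sensors (tens of thousands of
pixels, 1–4 px/mm) and photon budgets of 10⁴–2×10⁷ PE per frame — sized by
noise budgets so that each estimator's expected error sits well inside the
asserted tolerance, while a full suite completes in a few minutes on one
CPU. The hardness schedule is simulated at full length in the dose ledger
(27 000 pulses) with frames rendered every 50th pulse; rendering every
pulse changes only the computing cost, not the statistics of the recovered
slope.

## Known limitations

The simulator's flat field is ideal by construction (the real calibration
screen's own pre-calibration is out of scope), latency numbers are
configuration rather than measurement, the film comparison is abstract, and
the embedded stopping-power values are approximate single-medium constants
— override them for any medium other than water or energies outside the
table. The width interlock requires a configured reference width, since the
plan format carries no width column.
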