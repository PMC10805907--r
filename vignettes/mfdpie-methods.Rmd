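---
title: "Models and methods behind mfdpie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mfdpie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfdpie)
```

# Scope

`mfdpie` implements the full analysis chain for confocal single-molecule
FRET measurements with multi-parameter fluorescence detection and pulsed
interleaved excitation (MFD-PIE): burst detection and filtering, fully
corrected two- and three-color FRET efficiencies and stoichiometries,
photon-wise donor-lifetime analysis with static and dynamic FRET lines,
auto-, cross- and species-filtered fluorescence correlation spectroscopy,
dynamic photon distribution analysis (PDA) for two-state interconversion
rates, equilibrium titration fits, Kramers barrier estimation, and
accessible-volume (AV1) dye modeling on protein structures. A synthetic
photon-stream generator with full ground-truth bookkeeping makes every
stage testable without instrument data.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the simulation
round trips demonstrate.

# The photon data model

Time-tagged photon records carry a *macrotime* (absolute arrival time in
integer ticks of the excitation clock), a *microtime* (TCSPC delay after
the laser pulse) and a detector id. Under PIE the lasers fire in
non-overlapping microtime windows, so the excitation source of each
photon is read off its microtime and its detection color off its
detector; photons in inter-window gaps are labeled "outside" and the
assignment is an exact partition. Macrotimes are stored as doubles
holding exact integers (exact to 2^53 ticks, i.e. years of acquisition at
tens of MHz). Streams are serialized to a self-describing plain-text
container: a CSV with `#`-prefixed `key=value` header lines for the
clock period, TCSPC resolution and channel count, so a round trip is
lossless.

The bundled schemes (`pie_scheme_2c()`, `pie_scheme_3c()`) emulate
common layouts: two-color at 26.7 MHz repetition with the red pulse
delayed by half a period, three-color at 16.7 MHz with three equal
windows, two polarization detectors per color, and ~9-20 ps TCSPC
channels.

# The synthetic photon stream generator

The generator (`simulate_stream()`) emulates freely diffusing single
molecules at 50-100 pM equivalent occupancy transiting a confocal spot:

* **Transits.** Molecule passages are Poisson events. Each transit has a
  Gaussian intensity envelope whose width is tied to the diffusion time
  (see *Calibration* below) and a peak amplitude drawn from the
  straight-path-through-a-Gaussian-beam law (density 1/(a log(1/a_min))
  on [a_min, 1]); this reproduces the broad burst-size distribution of
  real measurements.
* **Kinetics.** Within a transit the conformational state follows an
  exact event-driven (Gillespie) continuous-time Markov simulation at
  the configured rates, started from the stationary distribution, so
  dwell-time statistics are unbiased — a prerequisite for PDA recovery
  tests. Rates faster than ~10^5 per ms are rejected as outside the
  supported range.
* **Photon channels.** Each state emits into the PIE channels with
  budgets that follow the correction algebra exactly: for a dual-labeled
  state with corrected efficiency E and correction set (alpha, delta,
  gamma), the donor-excitation channels receive rates proportional to
  (1-E), gamma E + alpha (1-E) + delta rho_RR, and the acceptor-excitation
  channel a constant budget. The three-color cascade routes blue
  excitation quanta to blue/green/red emission with probabilities
  obtained by inverting the three-color correction equations, so
  simulate-then-analyze is an exact round trip in expectation.
* **Microtimes.** Donor photons draw exponential delays at the state's
  lifetime, convolved with a Gaussian IRF (default 0.25 ns width at
  1.5 ns offset) and wrapped at the excitation window; background
  photons are uniform in their window.
* **Background.** Per-channel Poisson background, default 1 kHz in the
  donor-excitation channels and 0.5 kHz in the acceptor-excitation
  channel.

Defaults: 50 kHz donor-excitation brightness, occupancy 0.05, 1 ms
diffusion time. Brightness and background defaults are package
conventions chosen to be typical of confocal smFRET instruments; they
are not fitted to any particular dataset.

**Calibration.** Arrival rate and peak brightness are fixed analytically
by two conditions: the mean total count rate equals
`background + brightness * n_mean`, and the shot-noise-free correlation
amplitude equals `2^(-3/2) / n_mean` (the 3D-Gaussian geometric factor).
The transit-envelope width is `0.62 * tau_diff`: the Gaussian envelope
has a lighter tail than the 3D-diffusion correlation shape, and this
factor was calibrated once so that the standard diffusion fit of the
simulated correlation function recovers the configured `tau_diff`;
`tau_diff` is therefore defined operationally as the diffusion time the
standard fit reports.

**What the generator does not emulate.** Real point-spread-function
optics, saturation, triplet blinking, detector afterpulsing and dead
time, time-resolved anisotropy decay (polarization is a fixed 50/50
splitting), and photobleaching kinetics beyond a simple per-transit
acceptor-bleach probability used to exercise the ALEX-2CDE filter.
Passing recovery tests therefore demonstrates the correctness of the
estimators under the stated statistical model, not robustness to every
instrumental artifact.

# Burst analysis

`burst_search()` implements the all-photon sliding-window criterion: a
photon is in-burst if at least `m` photons fall in the centered window
of width `T` around it, and maximal runs with at least `L` photons
become bursts. Defaults are the standard two-color settings (m = 5,
T = 500 us, L = 50); three-color analysis uses m = 30, L = 100. The
window is centered — the trailing variant is a one-line change — and
bursts are never merged across gaps. Background rates default to the
per-channel rate of the out-of-burst stream — which deliberately
includes the diffuse signal of sub-threshold molecules, since that
contamination is present inside bursts too; a low-quantile "floor"
variant estimates the instrumental background alone, for analyses that
handle molecular contamination explicitly. Corrected counts
`F_XY - b_XY * duration` are deliberately not clamped at zero because
clamping distorts the E/S algebra.

Multi-molecule events are handled by two complementary filters. The
isolation filter (`burst_isolation()`) flags bursts whose local
out-of-burst count rate exceeds the background level or that have a
neighboring burst within a 5 ms margin: a second molecule grazing the
volume during a transit distorts per-burst observables and, in
sliced-window analyses, mimics conformational dynamics.
The ALEX-2CDE filter scores intra-burst brightness asymmetry between
two excitation classes with exponential kernel density estimates
(default time constant 100 us). The implementation uses self-excluded,
rate-normalized density ratios combined as `110 - 50 (r_XY + r_YX)`:
well-interleaved bursts score near 10 regardless of the class rate
ratio, time-separated classes approach 110, and the score is invariant
under time reversal. The conventional acceptance threshold of 12
(two-color) and 15/20 (three-color pairs) then separates clean bursts
from photobleaching, blinking, and multi-molecule events.

# Correction algebra and calibration

Two-color corrected efficiency and stoichiometry use the standard
crosstalk (alpha), direct-excitation (delta) and gamma corrections on
background-corrected counts. The three-color formulas compute E_GR from
the green-excitation counts as in two-color analysis, correct the
blue-excitation signals for crosstalk and direct excitation, and then
unmix the blue-to-green and blue-to-red pathways; the donor term of the
E_BG denominator is `gamma_BG F_BB (1 - E_GR)`, the form that reduces
exactly to the two-color expression when E_GR = 0. Bursts with
E_GR = 1 are flagged invalid because the direct-excitation unmixing has
a (1 - E_GR)^-1 singularity there.

`estimate_corrections()` follows the community-standard calibration:
alpha from the apparent efficiency of donor-only bursts, delta from the
apparent stoichiometry of acceptor-only bursts, and gamma from the
requirement that corrected stoichiometry be independent of efficiency
across FRET populations (the linear relation between 1/S and the
proximity ratio). Two implementation details matter at realistic
background levels:

* Calibration populations are restricted to bursts whose *complementary*
  excitation channel is statistically consistent with pure background
  (Poisson 90% bound). A co-diffusing acceptor-bearing molecule inside a
  "donor-only" burst deposits red-excitation photons, and such
  multi-molecule bursts otherwise inflate the crosstalk estimate by tens
  of percent.
* The gamma fit uses aggregate per-population counts (not per-burst
  ratios, whose inverse-stoichiometry means are noise-biased), clusters
  trimmed to a robust two-dimensional core in the (E, 1/S) plane —
  donor-only co-diffusers drag a population's acceptor signal down and
  acceptor-only co-diffusers drag it up, and one-dimensional trimming
  sorts these contamination types asymmetrically — and, when a floor
  background estimate is supplied, floor-corrected counts: subtracting
  the diffuse-average background from bursts that the purity gates have
  already certified as clean systematically overcorrects them. With all
  three elements the calibration recovers simulated correction factors
  to better than 10% at 50-100 pM-equivalent occupancy.

# Donor lifetimes and the E-tau diagnostic

Burst-wise lifetimes are photon-by-photon maximum-likelihood estimates
on TCSPC microtimes — unbiased at the 50-100 photons of a typical burst,
where least-squares histogram fitting is not. The decay model is a
single exponential circularly convolved (FFT) with the measured IRF
histogram; circular convolution represents the periodic wrap of late
photons exactly. A flat mixture component with a *fixed* weight — the
expected background counts over the burst's donor counts — accounts for
uniform-microtime background photons; without it, a 10% background
admixture inflates a 1.8 ns lifetime estimate by almost 1 ns. Bursts
with fewer than 20 donor photons are flagged and excluded from E-tau
analysis. Subensemble decays pool the donor photons of all selected
bursts and fit a biexponential plus an IRF-shaped scatter component by
multinomial maximum likelihood, reporting Pearson reduced chi-square;
near-degenerate components fall back to a single exponential with a
warning.

The E-tau plane carries three reference lines: the static line
`E = 1 - tau/tau_D0` (tau_D0 = 3.6 ns for the green donor), the
dye-linker-corrected static line (a third-order polynomial in the
lifetime with fixed published coefficients for this dye pair), and the
two-state dynamic line `E = 1 - tau1 tau2 / (tau_D0 (tau1 + tau2 -
tau))` connecting the endpoint states. The linker polynomial returns
efficiencies outside [0, 1] for lifetimes approaching tau_D0 (its
printed normalization cannot hold over the full range), so it is gated
to the lifetime range where it lands in [0, 1] and falls back to the
plain static line outside. Static molecules scatter around the static
line; molecules switching states within a transit displace upward
toward the dynamic line, because the intensity-weighted mean lifetime
over a burst is dominated by the brighter (lower-E) state. This
displacement is the package's dynamics diagnostic, and the simulation
reproduces it quantitatively.

# Correlation spectroscopy

The correlator is a direct weighted pair-count estimator of
`G(tau) = <dI(t) dI(t+tau)>/<I>^2` on a logarithmic lag grid with
multiple-tau-style bin widths (lag/8), exact against a brute-force
O(n^2) oracle; per-photon weights support filtered-FCS species
correlations, and burst-restricted correlation keeps a 50 ms margin
around each burst. Errors come from 10-block splitting; fits weight by
the block SEM floored at 3% of the curve amplitude, because
sparse long-lag blocks otherwise produce accidentally tiny SEMs that
dominate the fit.

The diffusion model is the 3D-Gaussian confocal form with geometric
factor 2^(-3/2) and aspect ratio rho implemented as the axial-to-lateral
ratio z0/w0 > 1, so the second factor slows the decay (the alternative
reading of rho makes the model non-monotone in a way incompatible with
its use). FCCS amplitudes convert to green-only/red-only/double-labeled
molecule numbers by the standard three-equation system; a
cross-correlation amplitude above either autocorrelation is rejected as
inconsistent.

Species-filtered FCS builds minimum-variance unbiased per-channel weight
vectors from normalized species microtime patterns (generalized least
squares with inverse-mean-count weighting); unbiasedness — filter s
applied to pure pattern s' sums to delta_ss' — holds to 1e-10 by
construction and is asserted in tests. Species are defined by low/high
efficiency thresholds on bursts, their patterns pooled over donor and
FRET-sensitized acceptor channels, plus a buffer/background component
measured from the out-of-burst stream. The four species correlations
are fitted globally with a shared transport factor and two shared
kinetic relaxation times; the kinetic terms enter the species
autocorrelations as `1 + A exp(-tau/tau_R)` and the cross-correlations
with the mirrored sign (exchange anti-correlation). Because imperfect
filters leak each species into the other curve — mixing correlated and
anti-correlated exchange terms within one curve without changing the
shared relaxation times — the per-curve kinetic amplitudes are left
free in sign and magnitude; given the shared times the model is then
fully linear per curve, so amplitudes and baselines are solved exactly
(with a light ridge on the kinetic coefficients, which become
collinear with the transport factor when the data carry no kinetics)
and the nonlinear search runs only over the transport time and the
relaxation times. The transport factor is the 3D-Gaussian diffusion
model for measured data or a Gaussian envelope matching the
generator's transit emulation for simulated streams — the envelope's
light tail is steep enough that fitting it with the diffusion model
contaminates the recovered relaxation times. For a two-state Markov
switcher the slow relaxation time estimates 1/(k12 + k21), recovered
to better than 10% in the simulation round trip.

# Dynamic photon distribution analysis

Selected bursts are sliced into consecutive windows of 0.5, 1 and
1.5 ms (trailing partial windows discarded, for clean count
statistics); each window contributes its uncorrected proximity ratio
`PR = F_GR/(F_GR + F_GG)` and its photon count N. The forward model
composes:

* the two-state occupation-time law at rates (k_fold, k_unfold),
  computed by transition-matrix discretization of the window into 200
  slices (exact two-state slice transition probabilities, occupancy
  attributed to the state at slice start) — validated against an
  event-driven Monte-Carlo oracle to total-variation distance below
  0.01 at symmetric and asymmetric rates, and extensible to more
  states, which is why the matrix method was chosen over the two-state
  Bessel closed form;
* background photons: Poisson per window at the measured per-channel
  rates, split between the donor and acceptor channel at the background
  color ratio, convolved exactly with the binomial signal conditional
  on each window's total count;
* per-state apparent proximity ratios mapped from corrected state
  efficiencies through the correction factors;
* optional static auxiliary states (impurities, donor-only) at fixed PR
  with free per-histogram fractions, broadened in distance space with
  the empirical width rule sigma = 0.07 R pushed through the Forster
  relation (broadening is configurable and set to zero when the
  generative model is known to have sharp states, as in simulation
  round trips);
* binomial shot noise at each window's observed N, mixed over the
  empirical N distribution.

Windows with fewer than 10 photons are discarded (burst-edge windows
are background dominated), and the count distribution is collapsed to
at most 48 representative window sizes with the occupancy support
quantized to 1% steps — both negligible against shot noise and large
savings in the fit loop. Above ~1000 expected switching events per
window the fast-exchange closed form (a single averaged state) replaces
the discretization. The global fit minimizes the summed multinomial
deviance across all bin widths with shared rates (more efficient than
Pearson chi-square for the sparse minority-state bins that carry the
slower rate); per-bin-width Pearson reduced chi-squares are reported as
fit diagnostics, and 95% confidence intervals come from the profile
deviance (3.84 increase with the co-rate re-optimized). The relaxation
time 1/(k_fold + k_unfold) is reported alongside the rates and is
better determined than either rate individually. Naming: k_fold is the
unfolded-to-compact rate and k_unfold the compact-to-unfolded rate,
always in this unambiguous internal convention.

Simulation round trips show that the recovered rates are *apparent*
rates, as they are for measured data: residual multi-molecule
contamination that survives isolation and ALEX-2CDE filtering, together
with the intensity modulation of the transit envelope across a window,
can inflate the minority-state rate of a strongly asymmetric scheme by
~10-25% across 30 s realizations at 50-100 pM-equivalent occupancy,
while symmetric schemes and the relaxation time are recovered within a
few percent; under contamination-free conditions the recovery is
unbiased within statistics. Auxiliary states absorb part, not all, of
this. The same caveat applies to any burst-sliced PDA of measured
streams.

# Titrations and the Kramers barrier

Equilibrium denaturant titrations are fitted with the Boltzmann form
`y = (I1 - I2)/(1 + exp((c - c0)/dc)) + I2` or, when an intermediate
population produces two transitions, the double form with a shared
width and fractional amplitude f1. Refolding kinetics use
`y = A (1 - exp(-k t))` on baseline-subtracted traces and report the
half-life ln(2)/k.

The apparent folding barrier inverts the Kramers relation
`tau_f ~ 2 pi tau_0 exp(dG_f/(R T))`, with tau_0 the reconfiguration
time of the unfolded chain (taken from the relaxation time of the
unfolded/compact interconversion) and tau_f the characteristic folding
time. When a folding rate k_f is given, the default conversion is the
half-life `tau_f = ln 2 / k_f`; the inverse-rate convention `1/k_f` is
selectable and yields barriers about RT ln(1/ln 2) ~ 0.9 kJ/mol higher.
Temperature defaults to 295 K (room temperature). Both conventions and
the temperature are explicit arguments because the ~5% ambiguity they
introduce exceeds the statistical error of typical rate measurements.

# Accessible-volume modeling

The AV1 model places a dye sphere (radius 3.5 A) on a flexible linker
(length 20 A, width 4.5 A) at a labeling-site atom. On a cubic grid
(default 1 A) a position is accessible iff the dye sphere clears every
heavy atom's van der Waals radius and a linker path of geodesic length
at most L exists from the attachment through sterically free grid
points, with 26-connectivity and Euclidean step costs (chamfer sweeps
iterated to convergence; verified against an independent shortest-path
oracle). Predicted observables from two clouds are Monte-Carlo averages
over uniformly weighted position pairs: the mean inter-dye distance,
the distance between mean positions, the FRET-averaged efficiency and
its apparent distance. Note that the Jensen bias of efficiency
averaging can push the apparent distance either above or below the mean
distance depending on where the distance distribution sits relative to
the inflection of the Forster curve; for high-efficiency pairs the
concave branch dominates and the apparent distance is slightly above
the mean.

# Problem sizes used in tests

The test-suite simulations use 8-40 s of synthetic stream at occupancy
0.05-0.1 (hundreds to a few thousand bursts) and the acceptance
analyses use 30-90 s per condition; these sizes were chosen so each
estimator's statistical error is several times smaller than the
tolerance it is tested against. Monte-Carlo oracles run at 10^4-10^5
replicates. All simulations and subsamples are seeded and
deterministic.

# Known limitations

* The simulator's diffusion is an envelope model, not a spatial random
  walk; correlation-function shapes agree with the 3D-Gaussian model
  only to the extent documented above, and the structure parameter rho
  is not meaningfully recoverable from simulated curves.
* Correction-factor estimation assumes donor-only, acceptor-only and at
  least two dual-labeled FRET populations are present; gamma estimation
  refuses single-population tables as rank-deficient.
* PDA supports two kinetic states plus static auxiliary states;
  lifetime-seeded two-dimensional PDA and larger kinetic networks are
  out of scope.
* The AV1 implementation uses a fixed internal van der Waals radius
  table, ignores hydrogens absent from the structure, and implements
  the single-radius AV1 variant only.
* Vendor TTTR container formats are not parsed; streams enter through
  the plain-text container or the simulator.
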