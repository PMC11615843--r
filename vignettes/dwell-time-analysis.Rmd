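---
title: "Single-molecule fluorescent-ATP dwell-time analysis: models, corrections and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule fluorescent-ATP dwell-time analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smatpase)
```

## The measurement this package models

In a TIRF assay of surface-attached myosin motor fragments on actin, a
fluorescent ATP analogue lights up a motor only while a nucleotide is bound:
each catalytic cycle appears as one intensity burst in a small region of
interest (ROI), and the distribution of burst ("on-dwell") durations carries
the turnover kinetics.  For a motor with binding rate constant $k_{on}$
(nM$^{-1}$s$^{-1}$) at fluorescent-ATP concentration $C$ and turnover rate
constant $k_{cat}$ (s$^{-1}$):

* waiting times between bursts are exponential with rate $k_{on} C$,
* burst durations are exponential with rate $k_{cat}$,
* bursts occur at the renewal rate $r = 1/(1/(k_{on}C) + 1/k_{cat})$.

An ROI holds one to a few motors, possibly of different kinetic classes
(actin-activated heads around 8 s$^{-1}$; basal-like heads near 0.05
s$^{-1}$), so pooled dwell times form an exponential mixture.  Dwells are
summarised as a complementary cumulative distribution — the number of dwells
of duration at least $t$ — and fitted with

$$y(t) = N \sum_i A_i e^{-k_i t}, \qquad \sum_i A_i = 1 ,$$

where $N$ is the total number of dwells.  The package implements this
pipeline end to end: an exact stochastic simulator of the binding/turnover
process per ROI, a camera model, threshold-based dwell measurement, the
fitting and model-comparison machinery, amplitude corrections, a synthetic
two-channel movie generator with ground truth, eGFP-based motor-density
quantification, and Monte-Carlo studies of digitization bias and sampling
variability.

## The stochastic simulator

`simulate_binding_events()` draws, independently per motor, alternating
exponential waits (rate $k_{on}^{hot} C_{hot} + k_{on}^{cold} C_{cold}$) and
bound dwells (rate $k_{cat}$) — the Gillespie scheme for this two-state
chain.  Non-fluorescent ("cold") ATP occupies the site invisibly; it defaults
off.  Photobleaching, when enabled, is a competing terminator of the
*visible* part of a hot dwell only; its default is zero because the
measured photobleaching rate in this assay (0.004 s$^{-1}$) is an order of
magnitude below the slowest kinetic rate of interest.  Events straddling the
end of the recording are truncated and flagged `censored`;
`simulate_dwells()` collects a fixed number of completed dwells.

Default rate constants (`reference_two_motor_model()`) are one fast motor
($k_{on} = 0.005$ nM$^{-1}$s$^{-1}$, $k_{cat} = 8$ s$^{-1}$) and one slow
motor ($k_{on} = 0.0025$ nM$^{-1}$s$^{-1}$, $k_{cat} = 0.05$ s$^{-1}$) at 5
nM fluorescent ATP.  Two values of the slow binding constant (0.0025 and
0.002) circulate for this model; the package defaults to 0.0025 — the value
attached to the reproduced simulation figure — and exposes the other through
`slow_k_on`.  With these numbers the fast motor contributes
$r_f = 0.0249$ s$^{-1}$ and the slow one $r_s = 0.0100$ s$^{-1}$, so 71.4%
of observed events are fast although the ROI holds one molecule of each —
the central reason event fractions must not be read as molecule fractions.

## Camera digitization and dwell measurement

`camera_spec()` defaults to a 52 ms frame-to-frame interval with a 50 ms
exposure.  Frame $i$ integrates fluorophore presence over
$[i\,\Delta t,\ i\,\Delta t + t_{exp})$; the 2 ms remainder is dead time, and
bound time falling there is invisible.  This dead-time treatment is implied
by the stated camera timings rather than documented anywhere; it matters
little at these rates but is modelled for fidelity.

`measure_dwells()` reproduces threshold-based manual scoring: candidate
events are contiguous runs of frames above an absolute floor (5% of the
one-fluorophore intensity; a single sub-floor frame splits events — no gap
closing), and within each candidate the frames at or above a threshold
fraction (default 0.5) of *that event's* maximum are counted, so the dwell is
a whole number of frame intervals.  Two opposed distortions follow:

* sub-frame events are normalised by their own small maximum, so even a
  10 ms binding scores one full frame (52 ms) — short dwells are inflated;
* edge frames with partial occupancy drop below the threshold, so some
  events lose their flanks.

## Why the fit is anchored at N, and what the bias study shows

`fit_multiexp()` fixes the fitted curve's value at $t = 0$ to the observed
event count $N$ (amplitudes live on the simplex; rates are positive;
Levenberg–Marquardt with multiple starts, including a sequential start that
extends the $(m-1)$-phase solution by one slower phase).  This anchoring is
deliberate and is not cosmetic: a complementary cumulative curve *must*
equal $N$ at zero, and only an anchored fit feels the systematic
lengthening that frame quantization imposes on measured dwells.  With a free
scale the lengthening is absorbed invisibly into the amplitudes and the bias
study would report nothing.  Anchored, the pipeline reproduces the headline
methodological result: simulating the reference two-motor model, digitizing
at 20 frames s$^{-1}$, measuring at threshold 0.5 and fitting a double
exponential underestimates the fast rate by about 25% (`bias_grid()`), the
underestimation worsening at lower thresholds and easing at higher frame
rates.  It also explains why subtracting half a frame interval from every
dwell (`half_frame_correct()`) helps: the subtraction shifts the data back
toward the anchored model.

In this implementation the half-frame correction reduces the magnitude of
the fast-rate bias in every grid cell with threshold below 0.5, but does not
always push it below 10% (at 20 frames s$^{-1}$ and threshold 0.3 it moves
roughly from $-31\%$ to $-19\%$): at low thresholds the per-event-maximum
rule adds close to a full frame per edge, more than the half frame the
correction removes.  The package states the reduction property, which is
what it can verify.

## Model comparison

Each fit reports $R^2$ and a least-squares AICc
($n\ln(\mathrm{RSS}/n) + 2K + 2K(K+1)/(n-K-1)$, $K$ = parameters + 1) for
compatibility with curve-fitting software.  `compare_models()`, however,
defaults to AICc built from the exponential-mixture log-likelihood of the
raw dwells, refit by EM per phase count.  The reason is statistical: points
of a cumulative curve are a running sum of the same $N$ observations, so
least-squares AICc treats one sampling fluctuation as hundreds of
independent residuals and will happily "detect" a second phase in pure
single-exponential data (differences of several hundred AICc units in
simulations at $N = 1000$).  The likelihood of the independent dwell times
has no such pathology: spurious phases cost more than they gain, while a
genuine 2% slow phase in a 1000-dwell three-phase sample is still found.  An
additional phase must beat the simpler model by more than 2 AICc units.
Confidence intervals on rates and amplitudes are asymptotic (from the
least-squares covariance, delta method for the simplex) and inherit the
serial-correlation optimism; the EM fit (`fit_multiexp_ml()`) serves as an
independent cross-check of the point estimates.

## Amplitude corrections

Observed amplitudes count events.  Two corrections convert them toward
molecule fractions:

* **Dwell-time weighting** (`correct_amplitudes_eq1()`):
  $A_i^{corr} \propto A_i / k_i$, the classical correction, exact when
  binding is fast and the event rate of a class equals its $k_i$.  When
  binding (not turnover) limits the event rate it *under*-weights fast
  classes, so corrected and observed values are reported as lower/upper
  bounds per phase.
* **Cycle-time weighting** (`cycle_corrected_fractions()`):
  $n_i \propto A_i / r_i$ with $r_i = 1/(1/(k_{on,i}C) + 1/k_i)$, which
  needs the binding constants but inverts the event-frequency distortion
  exactly: applied to the analytic event fractions (0.714, 0.286) of the
  reference model it returns (0.5, 0.5), and it reduces to the dwell-time
  weighting in the limit $k_{on} C \gg k_i$.

## The synthetic movie generator

`movie_spec()`/`place_motors()`/`render_movie()` emulate the recordings the
real pipeline consumes: a static eGFP channel (every motor carries one eGFP)
and a blinking fluorescent-ATP channel whose per-frame emitter intensities
come from the same simulator and camera model.  Motors are a Poisson
process along filament polylines with linear density = (motors per monomer)
× 362 monomers/μm — at a 1:50 ratio the mean spacing is 138 nm — plus a
uniform surface-adsorbed population.  The point-spread function is an
integrated 2-D Gaussian (σ = 0.13 μm ≈ λ/2NA for 660 nm at NA 1.49 — the
source recordings specify no PSF, so this is a package choice), normalised
so a fully bound frame integrates to the camera's unit intensity; pixels
are 0.2667 μm so a 3×3 ROI spans 0.8 × 0.8 μm².  Noise is Poisson on
signal + background plus optional Gaussian read noise.  Not emulated:
axial TIRF decay, defocus, drift, EMCCD excess noise, autofluorescence and
illumination inhomogeneity.  Passing round-trip tests on these movies
therefore validates the bookkeeping and the detection logic, not robustness
to every pathology of real recordings.

## Event detection and selection

`detect_events()` finds maximal runs of frames at least
`intensity_factor` (default 2) robust noise SDs above the robust background
(median / MAD of the ROI trace — the "twice the background noise level"
criterion, which the source protocol does not define numerically).  The
single-step requirement is operationalised as a coefficient-of-variation cap
(default 0.5) on the event's interior frames — the first and last frame are
partial exposures and are excluded from the plateau.  `apply_selection()`
enforces the recording- and ROI-level rules: recordings with more than 10
background events per 10 min are excluded wholesale, ROIs need strictly
more than 15 events, events must occur throughout the recording (largest
gap at most half the recording, configurable), and colocalization with the
static channel is required by default.  Every exclusion is logged.

A known consequence of the 2-SD default: with Poisson or Gaussian
background noise, isolated supra-threshold noise frames occur every few
hundred frames, so event-free traces are *not* free of detections at that
setting.  This mirrors the real protocol, which copes by excluding noisy
recordings rather than by raising the threshold; analyses on bright
synthetic movies (worked scripts under `analysis/`) raise
`intensity_factor` instead.  Claims that default detection yields fewer
than one false event per 10 minutes are not supported and not asserted.

## Density quantification

`single_molecule_intensity()` calibrates the intensity of one eGFP from at
least five isolated surface dots (3×3-pixel patches, background-subtracted;
dots closer than a patch are rejected).  `filament_density()` integrates a
filament's net intensity over a mask of configurable width (default 3
pixels) around its polyline and divides by the single-molecule value;
length × 362 gives monomers, whence the motor:monomer ratio and mean
spacing.  The default background estimator is the robust per-image median
rather than the minimum gray value (the minimum is biased by the noise
floor); minimum-value mode is available for fidelity to the original
procedure.  `motors_per_roi()` converts a spacing range to an occupancy
range: spacings of 0.138–0.837 μm against a 0.8 μm-wide, 1.13 μm-diagonal
ROI give 1–8 motors.

## Problem sizes and numerical choices

The shipped studies use 2000 events × 20 replicates for the 20-fps bias
figure, 1500 × 6 for the half-frame grid, 149 × 50 for the small-sample
fit-quality figure and 10⁴ idealized dwells for rate recovery — sizes at
which the Monte-Carlo error is a small fraction of the effects studied and
a full run completes in minutes on one core.  All randomness flows from one
integer seed per entry point.  Rates are sorted fast to slow after fitting
(ties broken by amplitude) to prevent label switching; amplitudes are kept
on the simplex by construction; non-convergent fits are flagged, never
silently dropped.  Degenerate inputs (empty motor lists, empty traces,
events in dead time, dark filaments) return empty or zero results rather
than errors wherever the empty result is meaningful.

## Known limitations

* The dwell-measurement rule is one reading of a manual procedure; real
  scoring by eye cannot be reproduced exactly, and all thresholds are
  exposed as arguments.
* Asymptotic CIs on cumulative-curve fits are optimistic; use the EM
  cross-check or bootstrap externally if CI coverage matters.
* The half-frame correction mitigates, but below threshold 0.5 does not
  eliminate, digitization bias under the per-event-maximum rule.
* No spatial kinetics (motors are point processes), no multi-step
  chemomechanical cycle, no hidden-Markov or changepoint dwell modelling.
* Experimental quantities that require the original recordings (per-dataset
  fitted ranges, pooled-data AICc values) are outside what synthetic data
  can reproduce; the studies here verify the *properties* those numbers
  illustrate.
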