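---
title: "Kinetic analysis of tRNA/T-box binding from smFRET traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of tRNA/T-box binding from smFRET traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tboxfret)
```

## The system and the model

A T-box riboswitch recognizes its cognate uncharged tRNA in two kinetic
steps: the tRNA anticodon is read first by the specifier loop in Stem I,
producing a *partially bound* complex, and the free 3' NCCA end of the
tRNA then docks onto the t-box bulge of the anti-terminator, producing
the *fully bound* complex.  With a donor dye (Cy3) on the 3' end of the
riboswitch and an acceptor (Cy5) on the 5' end of the tRNA, these states
appear as FRET efficiencies of roughly 0.4 and 0.7, with 0 for the
unbound riboswitch.

`tboxfret` treats the photophysical trace as the observable of a
continuous-time Markov chain (CTMC):

* **wild-type two-step scheme** (`scheme_wt()`):
  U ⇄ P ⇄ F with pseudo-first-order binding `k1·[tRNA]`
  (k1 = 5.0e5 M⁻¹s⁻¹), dissociation k₋₁ = 0.28 s⁻¹, docking
  k₂ = 10 s⁻¹ and undocking k₋₂ (see below);
* **NCCA-deleted ligand** (`scheme_dncca()`): the same first step with
  the fully bound state unreachable — the construct used to measure k₁
  and k₋₁ cleanly, because in the full scheme the partial-state sojourn
  is k₂-limited (~0.1 s) and carries no k₋₁ information;
* **K-turn deletion mutant** (`scheme_dkt()`): a branched four-state
  scheme in which the partially bound complex interconverts between a
  relaxed (FRET 0.2) and a bent (FRET 0.4) conformation of the
  riboswitch, and the fully bound state is reached either through the
  bent intermediate or directly.

Photobleaching is modelled as an independent absorbing exponential
process (not a scheme state), so the kinetic oracles — matrix
exponential occupancy (`occupancy_at_time()`), stationary distribution,
mean exit times — stay concentration-clean.  Association constants are
stored second-order and scaled by the ligand concentration when the
generator matrix is built, so the same scheme serves steady-state and
flow (injection) experiments.

## Choice of the undocking rate k₋₂

Only bounds are measurable for the wild-type second step: the fully
bound lifetime is photobleach-limited (τ₀.₇ > 24 s) and ~9 ± 5% of
bound traces show one or more visible excursions back to 0.4 — the
Type II fraction.  That observable pins k₋₂: an excursion lasts on
average 1/(k₂+k₋₁) ≈ 97 ms, below the frame time, so only a minority
of excursions is caught, and the visible fraction must be evaluated
through the full detection chain.  The default `k_rev = 0.004` s⁻¹ was
calibrated once by simulating the wild-type dataset, running the
complete pipeline (render → idealize → classify) and matching the
visible Type II fraction to the measured 9%; it is fixed thereafter
and configurable in `scheme_wt()`.  A value of 0.05 s⁻¹ (suggested by
chaining the ~150-fold equilibrium-change statement through the
bounded τ₀.₇) would predict visible excursions in ~40–50% of traces,
contradicting the measured fraction.

## Parameterization of the branched mutant scheme

The text pins only part of the branched scheme: the bent-state (0.4)
lifetimes toward 0.2 and 0.7 (0.30 s and 0.13 s → rates 3.33 and
7.7 s⁻¹), the fully bound lifetime (1.6 s), the association constant
(5.4e4 M⁻¹s⁻¹) and the composed apparent rates (k₂_app = 1.3 s⁻¹,
pooled k₋₁_app ≈ 0.21 s⁻¹).  The remaining rates were chosen once so
the composition reproduces those anchors: exits from the fully bound
state sum to 1/1.6 s⁻¹ and split 4:1 toward 0.4 versus 0.2 (the
transition-density populations), the relaxed→bent rate is 0.85 s⁻¹,
the direct 0.2→0.7 dock 0.2 s⁻¹, and dissociation from the relaxed
state 0.3 s⁻¹.  Note that the printed apparent undocking rate of
1.0 s⁻¹ cannot coexist with a 1.6 s fully bound lifetime under any
CTMC: the apparent backward rate is a convex combination of the two
exit rates whose *sum* is 1/1.6 = 0.625 s⁻¹.  The simulator follows
the lifetime; the estimator implements the published composition
formulas faithfully (`apparent_rates_dkt()`).

## Synthetic data: what is emulated, what is not

`generate_dataset()` draws exact Gillespie paths, independent
exponential bleach times for each dye, and renders frame-integrated
two-channel intensities: per 100 ms frame the FRET level is the
*time-weighted average* over the frame (not a point sample), acceptor
gets a bleed-through fraction of the donor signal, both channels carry
Gaussian read noise, donor bleach terminates all signal and acceptor
bleach zeroes FRET.  Frame integration is essential: it is what makes
sub-frame partial-state sojourns appear as intermediate FRET values and
reproduces the experimentally noted invisibility of most 0.4 sojourns
in the wild type.

Emission magnitudes are package conventions (total 1000 a.u., noise sd
50 a.u., bleed-through 0.1, baseline 0), as the experimental report
does not state them; they are exposed in `emission_model()` and all
FRET-level results are invariant to the total-intensity scale.  Not
emulated: camera pixelation and spot overlap, donor blinking,
non-Gaussian photon statistics, gamma (detection-efficiency) imbalance,
Mg²⁺ or temperature dependence.  A green end-to-end test therefore
establishes correctness of the *analysis chain* for data with the
stated statistical structure, not robustness to every optical artifact
of a real microscope.

Traces start in the unbound state at t = 0 (flow-like initial
condition).  For dwell statistics of exponential states this is
innocuous (memorylessness); tests that probe interconversion of the
branched mutant start molecules pre-bound, since at 30 nM the mutant's
mean binding wait (~600 s) exceeds the movie and the interconversion
rates are concentration-independent.

## Trace processing and selection

FRET is computed per frame as I_A/(I_D+I_A) after baseline and
bleed-through correction; frames whose total intensity falls below 10%
of the median are flagged invalid rather than divided.  Donor
photobleaching is located by a single change point maximizing the drop
in mean total intensity, and the trace is truncated there; the
truncated length feeds the trace-lifetime estimate (exponential MLE,
right-censored at the acquisition cap).

Spot selection emulates picking molecules from a maximum-intensity
projection of the acceptor channel: a trace is selected iff its
acceptor signal exceeds a threshold in at least one frame.  The default
threshold combines a signal criterion (half the 95th percentile of the
pooled signal) with a noise-floor criterion (4.5 robust sd), covering
both strongly and weakly binding constructs.  Two deliberate
conventions:

* selection uses the *whole movie* (the finite 70 s footprint window
  belongs to the f-vs-k₁ calibration, where it represents the
  bleach-limited signal horizon);
* the photobleach lifetime τ_trace is estimated from *all*
  donor-visible molecules, not the selected subset — conditioning on a
  detected binding event biases bleach times upward by the mean waiting
  time.

## Idealization

Each FRET trace is idealized per-trace with a Gaussian-emission hidden
Markov model trained by EM (Baum–Welch), the state count chosen by BIC
over 1–4 states, and the path decoded by Viterbi — a deliberate
substitution for the variational-Bayes tool used on the original data,
keeping the same contract (per-trace idealization, Gaussian emissions,
model-order selection) with fewer free hyperparameters.  Restarts
include quantile-based and jittered initializations plus, when the
canonical levels are supplied, one start at the levels with the
strongest support in the trace; this recovers sparsely populated states
near the time resolution.  Fitted means are then mapped to the nearest
canonical level (ties break toward the *lower* level, conservative
against overcalling bound states; fits farther than 0.15 from every
level are flagged unassigned).

## Dwell analysis and lifetime estimators

Dwells are maximal runs of identical canonical labels; the first and
last dwell of each trace are censoring-flagged.  The default lifetime
estimator is the censoring-aware exponential MLE
(τ = Σ durations / #uncensored); the classical histogram fit
A·exp(−t/τ)+y₀ is retained as `method = "histogram"` for parity with
the original analysis, whose free offset absorbs censoring crudely.
An optional geometric correction (`discrete = TRUE`) undoes frame
quantization when τ approaches the frame time.  Double-exponential
mixtures are fit by EM and summarized by the population-weighted
average lifetime (A₁t₁+A₂t₂)/(A₁+A₂).

Two estimator conventions matter for the association rate:

* τ₀₋₀.₄ is the naive mean of *uncensored first* waiting times.  Under
  competing exponentials (binding at k₁C versus bleaching at
  1/τ_trace) that mean estimates 1/(k₁C + 1/τ_trace), which is exactly
  what the photobleach correction
  k₁ = (1/τ₀₋₀.₄ − 1/τ_trace)/[tRNA] undoes; a censoring-aware MLE
  here would double-correct.  Interior rebinding waits are excluded
  because the deterministic acquisition cap truncates them
  asymmetrically.
* k₋₁ is read from the partially bound lifetime of the NCCA-deleted
  measurement, where that state is terminal.

## The f-vs-k₁ calibration

For weakly binding mutants, selected traces oversample fast binders,
so k₁ is instead estimated from the *fraction of molecules detected at
all*: `calibrate_f_curve()` simulates 2000 first-binding trajectories
per k₁ grid point, scores each by the footprint rule (any binding
event within the 70 s bleach-limited window), normalizes to the
reference construct and fits f = f₀ − a·e^{b·k₁} by scanning f₀ over a
grid and linear-fitting ln(f₀ − f) against k₁ (f₀ treated as a free
scan parameter, since the original fit does not say whether it was
fixed).  `invert_calibration()` solves the curve for k₁ with
first-order error propagation from the sd of f.  The published
reference curve corresponds to f₀ = 1.557, ln a = 0.45, b = −2.09 on
an abscissa of 10⁶ M⁻¹s⁻¹ — a unit fixed by the self-consistency
requirement that f = 1 maps to the wild-type k₁ ≈ 5×10⁵ M⁻¹s⁻¹.  The
simulated f is exactly insensitive to k₋₁ in this model because only
the first passage to binding decides detection.

## Apparent rates at finite time resolution

For the branched mutant, per-transition rates are the CTMC MLE
(events / exposure) on the idealized paths, pathway weights are
transition-count fractions, and the apparent docking/undocking rates
compose the two pathways.  Because the bent intermediate's true sojourn
(~0.09 s) sits below the 100 ms frame, these apparent rates are
*resolution-qualified* quantities: even perfect idealization of the
frame-discretized truth does not return the continuous-time
composition.  The acceptance suite therefore checks (i) the pooled
apparent dissociation rate — a slow, resolvable quantity — against the
analytic mean absorption time of the partial class, and (ii) the
docking composition against the same estimator applied to perfectly
idealized ground-truth labels of an independent replicate, isolating
the pipeline's own error from the resolution limit.

## Numerical choices

* FRET values are not clipped to [0,1]; the HMM emission model absorbs
  excursions (clipping would bias emission means).
* Histogram conventions: FRET bin 0.02 (1-D), 0.05 (TDP and
  post-synchronized), dwell histogram 30 bins; all config-exposed.
* Emission sd floor 1e-4 and a diagonal-dominant transition prior
  initialization (0.95) stabilize EM on short traces; EM stops at a
  relative log-likelihood change of 1e-6.
* One master seed drives everything; per-molecule, per-restart and
  per-stage seeds are drawn deterministically from it, and all derived
  seeds stay below 2³¹.
* Single-frame dwells are kept (flagged by `n_frames = 1`), matching
  the resolution discussion above; analyses can exclude them.
* Type classification excludes never-bound traces from the
  denominator, as the published percentages are fractions of bound
  traces.

## Known limitations

* The HMM is fit per trace; states visited only briefly in a given
  trace may be merged by BIC, which slightly inflates neighbouring
  dwell times (quantified in the branched-scheme acceptance test as a
  pipeline-vs-perfect-idealization comparison).
* No missed-event (time-interval-omission) correction is applied;
  rates within a factor ~3 of the frame rate are reported as apparent.
* Uncertainties are first-order (delta-method) propagations;
  molecule-level bootstrap is available only through re-simulation.
* The change-point bleach detector assumes a single dominant intensity
  drop; multi-step bleaching (e.g. two donors) is out of scope.
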