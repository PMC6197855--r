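# tboxfret

Kinetic analysis of tRNA binding to T-box riboswitches from
single-molecule FRET (smFRET) trajectories.

## The problem

T-box riboswitches are bacterial mRNA leader elements that bind a
specific uncharged tRNA and switch transcription read-through on.
Binding is a two-step process: the tRNA anticodon is recognized first by
Stem I (a *partially bound* complex, FRET ≈ 0.4 with a Cy3/Cy5 pair on
the riboswitch 3' end and tRNA 5' end), then the tRNA's 3' NCCA end
docks onto the t-box sequence (*fully bound*, FRET ≈ 0.7).  The kinetic
scheme is

```
            k1·[tRNA]          k2
        U  ──────────►  P  ──────────►  F        E(U)=0, E(P)=0.4, E(F)=0.7
        ◄──────────        ◄──────────
             k-1                k-2
```

with k1 ≈ 5×10⁵ M⁻¹s⁻¹, k₋₁ ≈ 0.28 s⁻¹, k₂ ≳ 10 s⁻¹ and k₋₂ near
irreversibility; a K-turn deletion mutant follows a branched scheme with
two partially bound conformations (FRET 0.2 and 0.4).  This package is
for single-molecule biophysicists who want a tested, fully synthetic
re-implementation of that analysis: exact continuous-time Markov chain
(CTMC) models with matrix-exponential oracles, Gillespie simulation
rendered as realistic two-channel camera traces (frame integration,
bleed-through, Gaussian noise, photobleaching), HMM trace idealization,
censored dwell-time statistics and the field's estimators for the rate
constants, including:

* k₋₁ = 1/τ₀.₄₋₀ from the partially bound lifetime of the NCCA-deleted
  ligand;
* the photobleach-corrected association rate
  k₁ = (1/τ₀₋₀.₄ − 1/τ_trace)/[tRNA];
* a simulation-calibrated estimator inverting the normalized detected
  fraction f through f = f₀ − a·e^{b·k₁};
* apparent docking/undocking rates composing the branched mutant's two
  pathways, k₂_app = p₁k₁'k₂'/(k₁'+k₋₁') + p₂k₂.

## Worked example

Simulate the first-binding-step experiment (NCCA-deleted tRNA, 30 nM,
100 ms frames, donor bleaching with mean 70 s) and recover the rate
constants end to end:

```r
library(tboxfret)

scheme <- scheme_dncca()                 # U <-> P only, k1 = 5e5, k-1 = 0.28
cond   <- experiment_condition()         # 30 nM, 100 ms, 1500 frames
model  <- emission_model(donor_bleach_rate = 1 / 70)

ds  <- generate_dataset(scheme, cond, model, n_molecules = 100, seed = 42)
res <- analyze_traces(ds$traces, canonical_levels = c(0, 0.4),
                      condition = cond, candidate_state_counts = 1:3,
                      seed = 43)
res$rates$k_off
#> k_-1 = 0.2411 +/- 0.025 s^-1 [reciprocal-lifetime]
res$rates$k_on
#> k_1 = 6.548e+05 +/- 1.7e+05 M^-1 s^-1 [photobleach-corrected]
res$lifetimes$tau_trace$tau
#> [1] 64.6
```

Both estimates recover the generating truth (0.28 s⁻¹ and
5×10⁵ M⁻¹s⁻¹) within two standard errors at this sample size: the
dissociation rate from the censoring-aware exponential MLE of the 0.4
dwell times, and the association rate from the mean first-binding wait
corrected for the ~65 s photobleach-limited trace length.  The same
`analyze_traces()` call on wild-type data also returns the Type I/II/III
trace classification, FRET histograms, transition-density data and
post-synchronized time-evolved histograms.

A command-line pipeline wraps the same steps
(`inst/scripts/tboxfret.R`):

```sh
Rscript inst/scripts/tboxfret.R simulate  --config cfg.json --out run/
Rscript inst/scripts/tboxfret.R analyze   --config cfg.json --traces run/traces.tsv --out out/
Rscript inst/scripts/tboxfret.R calibrate --config cfg.json --out cal/
```

Trace files use the two-columns-per-molecule (Cy3 then Cy5) delimited
layout; configs are flat JSON.

## Package layout

* `R/kinetic_models.R` — schemes, generator matrices, CTMC oracles
* `R/synthetic_data.R` — Gillespie paths, photobleaching, trace renderer
* `R/trace_processing.R` — corrections, FRET, truncation, spot selection
* `R/idealization.R` — per-trace Gaussian HMM (EM + BIC + Viterbi; C++ core)
* `R/dwell_analysis.R` — dwells, lifetimes, histograms, TDP, classification
* `R/rate_estimation.R` — rate-constant estimators and calibration curve
* `R/cli_pipeline.R` — orchestration and CLI
* `vignettes/tboxfret-methods.Rmd` — models, estimator conventions,
  design decisions and limitations
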