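---
title: "Quantification methods for soma-targeted optogenetic silencing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for soma-targeted optogenetic silencing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrquant)
```

## Scope

Optogenetic silencing studies with anion-conducting channelrhodopsins (ACRs)
quantify the same phenomenon — light-gated suppression of neuronal activity —
across very different data modalities: behavioral video, extracellular spike
trains, whole-cell voltage-clamp currents, light propagation through tissue,
and histological nuclei counts. `acrquant` implements that full quantification
stack as a set of small, testable primitives, together with synthetic-data
generators that emulate each input modality. The numbered scripts under
`analysis/` chain the stages into an end-to-end workflow over purely synthetic
inputs; every computational step lives in the package so it can be tested in
isolation.

Spike sorting, image segmentation, and acquisition-side processing are out of
scope: the package consumes sorted spike times, per-frame pixel-change counts
(or simple synthetic frame stacks), sampled current traces, and nuclei count
tables.

## Freezing classification

Freezing is operationalized as sustained absence of motion. The pipeline is:

1. **Frame differencing** (`pixel_change`): a pixel counts as changed when its
   intensity differs from the previous frame by more than `delta`
   (default 10 on the 0–255 scale; the criterion is rarely reported by
   tracking software, so it is an exposed configuration value). In ROI mode
   only changed pixels inside a dilated bounding box around the tracked
   animal blob are counted, which discards patch-cord motion. The tracker
   prefers the largest moving blob overlapping the previous ROI and retains
   the previous ROI when the animal is still; it can be seeded with a known
   initial region. If no blob has ever been seen the count falls back to the
   whole frame with a warning.
2. **Temporal smoothing** (`smooth_trace`): Gaussian kernel with
   `sigma = 3` frames, truncated at ±4σ and renormalized to sum 1, with edge
   replication. Renormalization makes constant traces exact fixed points;
   edge replication avoids spurious low values at session boundaries that a
   zero-padded convolution would produce.
3. **Run-length thresholding** (`detect_freezing`): a frame is freezing
   exactly when it lies in a run of at least `min_run` consecutive frames
   strictly below the threshold. The canonical parameters are 38 frames
   (1.5 s at 25 fps, `min_run_from_duration`) below 983 pixels for
   whole-frame traces — 0.5 % of a 512 × 384 frame, the default geometry —
   or below 100 pixels for ROI-restricted traces. "Below" is strict: a value
   exactly at the threshold counts as motion (the convention is not dictated
   by the rule itself; ties are measure-zero for real traces but must be
   fixed for reproducibility). The package warns when a global-mode
   threshold deviates from 0.5 % of the configured frame size by more than
   10 %.
4. **Windowed percentages** (`percent_freezing`): per conditioned-stimulus
   (CS) window and per 30 s pre-CS window, 100 × freezing frames / window
   frames, plus early/late phase means (first versus last `phase_n` CS).

Frame intervals are half-open `[start, end)` with 0-based frame indexing
throughout.

## Extracellular silencing analysis

Spike datasets hold trial-aligned timestamps (light onset at t = 0) with a
protocol: 5 s illumination, 10 trials per light power density (LPD) for the
long-pulse analyses; 5 ms pulses with 20 trials for the antidromic analyses.
All windows are half-open; a spike exactly at onset belongs to the light
window.

- `classify_suppressed`: paired two-tailed t-test on per-trial spike counts,
  5 s pre-light vs 5 s light window. A unit is *suppressed* when p < 0.05
  **and** the light-window mean is below the pre mean. The directional
  condition is a deliberate design choice: a pure two-tailed criterion would
  also flag units that increased their rate. It makes the classifier
  conservative — its empirical type-I rate on null units is roughly half the
  nominal α (about 2–3 % at α = 0.05), which the acceptance suite checks
  against the 5 % bound.
- Degenerate count vectors never crash the test: all-zero paired differences
  give p = 1 (never flagged); zero-variance nonzero differences give p → 0
  with a degeneracy note.
- `relative_fr`: pooled light-window rate over pooled pre-window rate;
  undefined (and excluded from population means) when the pre rate is zero.
- `psth_relative`: 100 ms bins tiling `[-pre, light + post)`, each unit's
  binned rate normalized by its own mean pre-light rate, then averaged
  across units.
- `classify_antidromic`: the same paired-count test on 20 ms windows around
  the onset of a 5 ms pulse, flagged for *increases*; mean first-spike
  latency is averaged over trials with at least one spike in the 20 ms
  window. Units are ordered by that latency (`latency_order`), ties broken
  by unit id. No minimum responsive-trial fraction is imposed.
- `population_summary`: fractions of flagged units per group and pairwise
  2 × 2 comparisons — Pearson chi-square without continuity correction when
  all cells are positive, Fisher's exact test otherwise. The
  no-continuity-correction choice is validated by exact reproduction of the
  five published construct-comparison statistics (20.61, 20.77, 6.59, 8.91,
  9.58) from the printed unit counts, reconstructed as `round(pct · n /
  100)` (`reference_unit_counts`).

## Photocurrent and EPSC quantification

- `stationary_current`: mean baseline-subtracted current over the last
  10 ms of a light pulse (the pulse-end averaging window is not specified by
  the convention "current at the end of a 1 s pulse"; 10 ms averages enough
  samples at 20 kHz to suppress noise without touching the decay). The
  measure is invariant under additive holding-current offsets.
- `fit_tau_off`: nonlinear least squares (Levenberg–Marquardt via
  `minpack.lm`) of I(t) = I₀ e^(−t/τ_off) + C on the post-offset decay.
  Initialization: C from the trace tail, I₀ from the offset-to-tail drop, τ
  from the observed 1/e crossing. Failures return `converged = FALSE`
  rather than throwing; a flat segment is flagged degenerate.
- `fit_epd50`: least-squares fit of the saturation law
  I(LPD) = I_max · LPD / (EPD50 + LPD), requiring ≥ 3 distinct LPDs. By
  construction the fitted curve passes through I_max/2 at LPD = EPD50.
  Large residuals (e.g. non-monotone inputs) set a `poor_fit` flag.
- `epsc_amplitude`: the trace is smoothed with an 11-point, second-order
  Savitzky–Golay filter using Welch (parabolic) window weights
  w_k = 1 − (k/6)², implemented as weighted local polynomial regression
  (classic Savitzky–Golay is the unweighted special case; the weighted
  variant is honored exactly, and edge samples use truncated windows). The
  amplitude is the maximal absolute deviation of the smoothed trace from
  the pre-light smoothed baseline within 20 ms after light delivery,
  reported as a magnitude. An order-2 filter reproduces constant, linear and
  quadratic signals exactly, which the tests exploit.

Sign convention: ACR photocurrents at V_hold = −35 mV are outward
(positive); EPSCs are reported as magnitudes.

## Tissue optics

`fractional_irradiance` factorizes into a geometric cone-spread term — from
fiber radius r, numerical aperture NA and tissue index n, with
ρ = r · sqrt((n/NA)² − 1) and I(z)/I(0) = ρ²/(z + ρ)² — and a
Kubelka–Munk-type scattering term 1/(S(λ) z + 1) with optional Beer–Lambert
absorption. S(λ) follows a power law around a reference wavelength
(defaults: S = 11.2 mm⁻¹ at 473 nm, exponent 1.4 — representative rodent
gray-matter values from the fiber-optics modeling literature, shipped as
editable parameters rather than claims about any particular preparation).
Transmittance is 1 at z = 0, strictly decreasing in depth and increasing in
wavelength.

`optimal_wavelength` maximizes spectrum(λ) × transmittance(z, λ); at z = 0 it
returns the spectrum peak, and the optimum red-shifts with depth whenever
transmittance increases with wavelength. The magnitude of the shift depends
on the spectrum's width and the scattering slope: for broad (σ ≈ 40 nm)
spectra under the default parameters it is a few nanometers at 0.5–1 mm.
Published estimates of light power at an electrode 500 µm below a fiber tip
depend on the exact parameterization of the optics model used, which is why
no specific transmittance value is treated as a test anchor; the bundled
spectra under `inst/extdata/` are synthetic unimodal stand-ins (so labeled)
for use in examples and the workflow scripts.

## Histology metrics

`lateralization_ratio` pools counts over the regions of one class:
Σipsi / (Σipsi + Σcontra) — 0.5 under hemispheric symmetry, 0 when all
nuclei are contralateral. Pooling before the ratio follows the definition of
normalizing to the *sum* of nuclei in a region class; because the
alternative reading (mean of per-region ratios) is not fully excluded by
that phrasing, it is available via `per_region = TRUE`. `dapi_cr_er_ratio`
applies the same normalization to DAPI counts as a cell-density control, and
`layer1_restriction_index` and `normalize_to_reference` implement the
fluorescence-based expression metrics (layer-1/center ratio; fold of a
reference mean).

## Statistics engine

All procedures are implemented in the package; base R equivalents, where
they exist, serve as independent cross-checks in the test suite:

- `chi2_2x2`: Pearson statistic without Yates correction, df = 1. A zero
  cell is an error that directs the caller to `fisher_exact_2x2` (two-sided
  p by summing hypergeometric probabilities not exceeding the observed
  table's).
- `mann_whitney_u`: exact mode enumerates the null distribution of U by the
  classical box-partition recurrence (untied data, min(n₁, n₂) ≤ 10);
  `normal_cc` mode uses the normal approximation with a 0.5 continuity
  correction and tie-corrected variance. The one-sided `normal_cc` path
  exists because published U/p pairs of the form U = 19, n = 8 vs 8,
  p ≈ 0.09 are jointly consistent only with that variant; the default
  remains two-sided.
- `kruskal_wallis`: H with tie correction, chi-square reference with k − 1
  df.
- `scheirer_ray_hare`: joint ranking (mean ranks for ties), two-way ANOVA
  sums of squares on the ranks, H = SS_effect / MS_total with
  MS_total = SS_total/(N − 1), chi-square reference with the effect's df.
  Main effects and the interaction are all returned even where only main
  effects are typically reported. Empty design cells are rejected.
- `paired_t`, `rm_anova_oneway`: textbook implementations with explicit
  degenerate-input handling (all-zero differences → p = 1; zero error
  variance → F = 0 or ∞ with a note, never NaN).
- `holm_bonferroni`: step-down adjustment with running-maximum monotonicity
  and capping at 1.

Calibration of the approximate tests is part of the acceptance suite: under
matched null simulations (2 × 2 design with 10 observations per cell for the
rank two-way ANOVA; three groups of 15 for Kruskal–Wallis; 2000 replicates
each) the empirical rejection rates at α = 0.05 fall within ±1.5 percentage
points of nominal.

## Synthetic data: what it emulates and what it does not

The generators are first-class, tested code. Design choices:

- **Spikes** (`gen_spike_dataset`): inhomogeneous Poisson by thinning
  against the max-rate bound r₀ · max(1, 1 + g). The rate is r₀(1 − s)
  during light, relaxes as r₀(1 + g e^(−Δt/τ)) after offset (rebound is a
  multiplicative exponential transient; gain 0 by default so it is opt-in),
  and r₀ elsewhere. Refractoriness is ignored — no spiking model beyond the
  rate profile is assumed by the downstream analyses. Antidromic events are
  inserted independently of the Poisson background at onset + latency
  (Gaussian jitter truncated at 0). `responsive_fraction` models expression
  heterogeneity: only that fraction of units is modulated at all, which is
  what makes population fractions of suppressed units realistic rather than
  saturating at 100 %. Baseline rates are 5 Hz by default, optionally
  log-normally dispersed — a convenience, not a claim about real rate
  distributions, which the source protocols do not characterize.
- **Behavior** (`gen_pixel_trace`, `gen_frame_stack`): truncated-Gaussian
  changed-pixel counts, high outside scheduled freezing bouts and near zero
  inside; optionally a patch-cord artifact component. Frame stacks render a
  random-walk disc "mouse" (stationary during bouts, never a zero step
  otherwise) plus an optional cord line confined to a band disjoint from
  the mouse region, so ROI and global traces can be compared exactly.
- **Currents** (`gen_current_trace`): photocurrents rise mono-exponentially
  to the saturation-law stationary level and close with τ_off; EPSCs are
  delayed difference-of-exponentials deflections; Gaussian noise; 20 kHz
  default sampling.
- **Histology** (`gen_region_counts`): per-region Poisson counts, with the
  ipsilateral suppression factor applied to c-Fos in expressing regions
  only. With factor f the expected expressing-class ratio is f/(1 + f).

Determinism: one global integer seed; every (unit, trial) slice draws from a
sub-stream derived deterministically from it, so outputs are reproducible
and order-independent. Identical configurations yield identical outputs.

What passing tests on these data do **not** show: the generators contain no
bursting, refractoriness, electrode drift, sorting errors, video compression
artifacts, or biological photocurrent desensitization. Parameter-recovery
and calibration results therefore demonstrate correctness of the estimators
under their assumed models, not performance on raw recordings; the measured
biology (absolute photocurrent amplitudes, freezing percentages, per-group
test statistics of real cohorts) is intentionally outside what desk-scale
synthesis can reproduce.

## Problem sizes and numerical choices

The test and acceptance workloads use sizes chosen to make Monte-Carlo error
small relative to each tolerance while keeping the full suite fast: 1000
null units for classifier calibration (binomial SE ≈ 0.7 % at 5 %), 100
seeds for kinetics/saturation recovery, 200 units for rate-ratio recovery,
2000 replicates for test calibration, 1000 random traces for the freezing
oracle equivalence. Nonlinear fits run Levenberg–Marquardt with analytic
initialization as described; all equality checks against oracles use 1e−9
relative tolerance or tighter unless an approximation is itself under test.
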