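---
title: "Cuffless blood-pressure estimation with GP-scored feature decision: models and methods"
author: "cghofd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation with GP-scored feature decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cuffless blood-pressure estimation infers systolic (SBP) and diastolic (DBP)
pressure from signals that can be measured continuously and non-invasively:
the electrocardiogram (ECG) and the finger photoplethysmogram (PPG). The
physical link is pulse transit time: the pressure pulse travels faster along
a stiffer (higher-pressure) arterial tree, so timing features such as the
pulse arrival time (PAT, the delay from the ECG R-peak to PPG landmarks) fall
as pressure rises. Morphology of the PPG pulse — amplitude ratios, sub-areas,
derivative shapes — carries complementary information about vascular tone.

This package implements the full chain: synthetic data generation,
preprocessing, extraction of 25 pulse features, three feature-weighting
filters, Gaussian-process (GP) regression, and a wrapper — the hybrid optimal
feature decision (HOFD) — that uses cross-validated GP RMSE to decide how far
down the weight-ranked feature list to keep. Evaluation follows the AAMI and
BHS device protocols.

## Preprocessing

Records are synchronized ECG/PPG/ABP triplets at 125 Hz (ABP, the invasive
arterial-pressure waveform, supplies the reference SBP/DBP). The chain is:

1. **NaN removal** at the union of per-channel NaN indices, so channels stay
   aligned.
2. **Band-limiting** with Kaiser-window FIR filters: low-pass at 35 Hz
   (high-frequency noise) and high-pass at 0.0665 Hz (baseline wander). The
   named cutoffs do not determine a filter; we design for 60 dB stopband
   attenuation with transition widths of 5 Hz (low-pass) and 0.05 Hz
   (high-pass), and apply the symmetric kernel in a single centered pass,
   which is exactly zero-phase — essential because every feature downstream
   is a timing measurement. Edges are padded by even (mirror) reflection:
   these signals oscillate about a baseline, and odd reflection would invert
   pulses at the boundary and bias the local baseline estimate. ABP is
   low-passed only; high-passing would destroy its mmHg calibration.
3. **Segmentation** into non-overlapping 20 s windows (0-based, half-open)
   after skipping the first 60 s of each record.
4. **Gating.** Windows are discarded when (a) a channel's min or max is an
   outlier among the record's windows — beyond the median ± 4 × IQR of the
   per-window extremes, with the IQR floored at 1 % of the typical window
   range so that near-identical clean windows are not flagged on noise-level
   jitter — or (b) the window's ABP extremes leave the physiological range
   (SBP ≥ 180 or ≤ 80, DBP ≥ 130 or ≤ 50 mmHg). The gate basis is a design
   choice: a record-level IQR is dominated by the inter-pulse baseline of a
   spiky signal like the ECG and rejects everything; the distribution of
   window extremes measures exactly the quantity being gated.

## Features

Per cardiac cycle, six fiducials are found: the ECG R-peak; the PPG foot
(diastolic trough), maximum-slope point (first-derivative peak on the rise),
systolic peak, falling-edge inflection (second-derivative maximum between the
systolic peak and the next foot — the shoulder left by the reflected wave),
and the next foot. From them the 25 features: systolic/diastolic times ST and
DT, intensity ratio PIR, heart rate HR and its frequency reading FHR (by
their definitions — HR the inverse R-R interval in beats/s, FHR the same
quantity in Hz — these coincide numerically; both columns are kept because
the downstream contract names both), arrival times PAT1–PAT3 (R-peak to
systolic peak, max-slope point, and next foot), stiffness index LASI,
augmentation index AI, pulse sub-areas S1–S4 and their ratio IPAR =
S4/(S1+S2+S3), the normalized mean-height PPGk = (pm − pd)/(ps − pd),
first/second-derivative heights and half-height widths, amplitude extremes
MXAP/MIAP, and a blood-viscosity surrogate MEU. The viscosity feature has no
closed-form definition in the accessible literature; the default surrogate is
ps/pm (pulse max over pulse mean), it is a plug-in, and it can be excluded.

Design choices worth stating: the per-segment feature is the **median over
the segment's cycles** (robust to a single bad beat); derivatives are central
differences scaled by the sampling rate; widths are measured at half the
relevant extremum's height with linear interpolation; PIR and AI are computed
on the per-segment min-max-normalized PPG. Cycles whose landmarks cannot be
resolved in the required order are dropped, never fabricated. The reference
SBP/DBP of a segment are the means of per-cycle ABP maxima/minima.

A caution on flat regions: the PPG foot and the falling-edge inflection are
extrema of nearly flat stretches, so under additive noise their sample
position is genuinely ambiguous over several samples even when detection is
working perfectly. The tests assert exact (±3 sample) agreement with ground
truth on noise-free signals and wider, landmark-appropriate tolerances under
noise.

## Feature weighting

Three interchangeable filters produce a full ranking (the wrapper consumes
rankings, never thresholded subsets):

* **F-test.** Observations are grouped by response value — rounded to the
  nearest mmHg, with undersized groups merged into the nearest group
  (quantile binning is available) — and each feature is scored by the one-way
  ANOVA F ratio of between-group to within-group mean squared deviation. The
  weight is −log10 of the p-value under the F(m−1, n−m) reference; p < 0.05
  flags significance.
* **NCA regression / robust NCA.** Feature weights w minimize the
  leave-one-out soft-neighbor loss: with weighted distance
  D(i,j) = Σ w²ₘ|xᵢₘ − xⱼₘ| and kernel exp(−D/σ), each point's response is
  predicted by its soft neighbors and the expected pairwise loss is averaged,
  plus λΣw²ₘ. The robust variant uses the bounded loss
  ζ(yᵢ,yⱼ) = 1 − exp(−|yᵢ − yⱼ|), capping outlier influence, and tunes λ by
  5-fold cross-validation over a grid (default 20 points in [0, 2·sd(y)/n];
  the CV score of a fold is the mean robust loss between held-out responses
  and their soft-neighbor predictions). Choices the method statement leaves
  open, fixed here: features are standardized and σ = 1; optimization is
  gradient descent with Armijo backtracking from an all-ones start (accepted
  iterates are non-increasing by construction, which the tests assert);
  objective and analytic gradient are in C++ (O(n²p) per evaluation) and the
  gradient is verified against finite differences. The classical fixed
  threshold (keep w ≥ 3) is reported for reference but deliberately not used
  for decisions — replacing it is the wrapper's purpose.
* **MRMR.** Greedy forward ranking by the mutual-information quotient
  MIQ = I(x,y) / meanᵤ I(x,u) over the selected set: most relevant feature
  first, then any zero-redundancy relevant features, then greedy MIQ, with
  zero-relevance leftovers appended in seeded random order. MI is the plug-in
  estimator over equal-frequency bins (default 10; columns with few distinct
  values are used as-is). The estimator is a design choice — the method
  statement names none.

## GP regression

The regressor is a GP with squared-exponential kernel
k(x,x′) = a·exp(−‖x−x′‖²/2η²), observation noise σ², and an explicit basis
(default: intercept only; linear optional). The kernel amplitude a and the
noise σ² are kept as two distinct positive hyperparameters — a single shared
variance would make the marginal likelihood ill-posed. Basis weights have a
closed-form generalized-least-squares maximizer and are profiled out; the
remaining three hyperparameters are optimized in log space by L-BFGS-B with
analytic gradients (valid at the profiled optimum by the envelope theorem),
from a data-driven start (median pairwise distance, response variance) with
seeded multiplicative restarts (default 3). Factorizations use a jitter
ladder 0 → 1e−10 → 1e−8 → 1e−6 of the mean diagonal before failing. Inputs
are standardized inside the model (stored, so prediction is transparent);
whether to standardize is not specified by the method statement and this is
the recorded choice. Predictions are posterior means — the optimal point
estimate under squared loss; the latent predictive variance is available but
unused by the wrapper.

## The wrapper (HOFD)

Given the ranking from the configured filter, for every prefix size from
`start_size` (default 25) down to `min_size` (default 2) the top-ranked
prefix is scored by 5-fold cross-validated GP RMSE. The fold partition is
drawn once per run from the seed and reused for every size, so differences
along the curve reflect subsets, not fold luck. The decided subset is the
prefix whose recorded mean CV RMSE is minimal, ties broken toward fewer
features. Two ambiguities in the method statement are resolved as: the
decision is literally the argmin of the recorded curve (no index
arithmetic), and the loop stops at size 2 by default (configurable to 1).
Inside the CV loop the GP uses one start and 40 optimizer iterations — subset
comparison is robust to slightly unpolished likelihood optima, and this keeps
the wrapper tractable; the final refit on the decided subset uses the full
3-start, 100-iteration budget.

`run_pipeline()` wraps the protocol: an 80/20 train/test split under the
seed, wrapper and refit on the training split, evaluation on the held-out
split, optionally repeated R times with derived seeds and averaged metrics
(R = 30 reproduces the published protocol shape; 1 is the desk default).

## Evaluation

From paired (predicted, reference) pressures: ME, its standard deviation SDE
(sample convention, n−1 — the divisor is a recorded choice), MAE, RMSE, R²,
the AAMI pass rule |ME| < 5 mmHg and SDE < 8 mmHg (strict inequalities, as
worded), BHS cumulative percentages of |error| ≤ 5/10/15 mmHg with grades A
(60/85/95), B (50/75/90), C (40/65/85), Bland–Altman bias and limits
ME ± 1.96·SDE, and one-way ANOVA comparison of per-repeat RMSE samples
across algorithms (identical groups return F = 0, p = 1 rather than 0/0).
A useful internal identity, asserted property-style in the tests:
RMSE² = ME² + ((n−1)/n)·SDE².

## The synthetic world

The waveform generator emulates what the method needs and nothing more:

* ECG: one narrow Gaussian QRS-like bump per cycle.
* PPG: an asymmetric two-Gaussian pulse (systolic bump + smaller, wider
  reflected/diastolic bump) — the simplest shape with a genuine falling-edge
  inflection, so LASI, AI and the four sub-areas are well defined. The pulse
  train lags the R-peaks by 250 ms + slope·(SBP − 120), slope −2 ms/mmHg by
  default: the order of magnitude is physiological, and only the sign
  matters for the monotonicity properties the tests check.
* ABP: a pulse rescaled to oscillate exactly between the configured DBP
  (trough) and SBP (peak), so reference extraction has an exact oracle.
* Optional Gaussian jitter on cycle length (default 0) makes HR features
  nontrivial; additive Gaussian noise per channel, default 0.

Ground-truth fiducials are read off the noise-free channels per interior
cycle, with the next-foot of one cycle literally the foot of the next, and
emitted alongside the signals. What this world does **not** contain —
arrhythmia, motion artifacts, sensor drift, baroreflex dynamics, real
inter-subject morphology variation — bounds what a green test establishes:
correctness of the implementation against its stated contracts, not clinical
performance. The published error statistics are defined on a large
bedside-monitor extract that cannot be bundled; accordingly the acceptance
suite is property-based (oracle equivalence, protocol worked examples,
seeded recovery rates) and `scripts/acceptance.R` reports no numeric targets.

The feature-table generator is a second, simpler world for the selection
stack: standard-normal features, a sparse linear target over a known support,
optional redundant columns that are noisy copies of support members. Recovery
claims in the tests (e.g. the wrapper retrieves the full support in ≥ 80 % of
seeds) are statements about this world.

## Numerical and degenerate-input policy

Division by zero in a feature (e.g. a foot amplitude of exactly 0 after
normalization) yields NaN for that cycle; the per-segment median absorbs
isolated cases and rows still containing NaN are dropped at assembly.
Constant series are rejected by normalization; flat ECGs signal "no cycles";
records whose windows are all gated signal "record excluded". All RNG flows
from user-visible seeds through stage-labeled derived seeds (kept below
2³¹), so every stage is independently reproducible and end-to-end reruns are
bit-identical — asserted via manifest checksums.

## Known limitations

* The viscosity surrogate is not the literature formula (which is not
  publicly specified); treat MEU as a configurable placeholder.
* The fixed-threshold RNCA report (w ≥ 3) is faithful to the classical rule
  but its scale depends on feature standardization; it is reporting output
  only.
* The wrapper's cost grows as (start_size − min_size) × folds GP fits; at
  desk scale this is seconds to minutes, but large cohorts warrant a larger
  `gp_opts$maxit` budget only if the RMSE curve looks unstable.
* The WFDB interface is a minimal format-16 writer/reader pair sufficient
  for round-tripping records with standard tooling, not a full
  implementation of the header dialect.
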