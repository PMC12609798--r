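---
title: "Estimating perceived exertion from force-time curves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating perceived exertion from force-time curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repforce)
```

## The estimation problem

During repeated sets of isokinetic bench press, the machine's load cell
records a force-time curve for every push. After each set the lifter
reports a rating of perceived exertion (RPE) on the OMNI-RES scale
(0 = "extremely easy" to 10 = "extremely hard"). The analysis this package
implements asks: can the end-of-set RPE be predicted from the force signal
alone, and which representation of the signal carries the information?

The pipeline is: simulate (or load) per-set force traces; low-pass filter;
segment into repetitions; normalize by body size; extract per-repetition
biomechanical descriptors; aggregate to the set level; append inter-set
relative features; screen, fit and discretize; evaluate out of fold with
subject-grouped cross-validation.

## The synthetic cohort: a stated world

Study-grade force/RPE datasets are typically proprietary, so the package
ships a generator whose statistical structure matches what the analysis
assumes, with ground truth retained so that every downstream stage can be
tested against the generator's own bookkeeping rather than against itself.

### Subject profiles

Each subject is drawn once from population distributions
(`population_params()`), and both limbs derive from the one profile:

| field | meaning | default (mean, SD) | bounds |
|---|---|---|---|
| `body_mass_kg` | body mass m in F/m^0.67 | 74.4, 11.58 | >= 40 |
| `base_peak_force_N` | unfatigued per-limb push force | 350, 70 | >= 50 |
| `fatigue_rate` | fractional work decline per set | 0.05, 0.02 | [0.005, 0.2] |
| `variability_gain` | growth of force-noise SD per set | 0.05, 0.02 | >= 0 |
| `noise_sd_frac` | force-noise SD / base peak | 0.03, 0.01 | >= 0 |
| `plateau_frac` | post-peak plateau level | 0.80, 0.05 | [0.6, 0.9] |
| `rpe_intercept` | RPE at zero fatigue | 4, 0.8 | [0, 10] |
| `rpe_fatigue_gain` | RPE units per unit latent fatigue | 20, 3 | >= 0 |
| `limb_asymmetry` | right-limb force deficit | 0.10, 0.05 | [0, 0.3] |

The body-mass moments are the published cohort description for this kind of
study (trained adult men); the force scale corresponds to a per-limb share
of a 7RM bench-press load for that population; the fatigue rate gives a
~26% work decline over 7 sets, consistent with reported significant
work differences between the first and last set. Out-of-bound draws are
clipped rather than rejected so a fixed seed always yields a cohort of the
requested size.

The `coupling = "strong"` preset shrinks the intercept SD to 0.3 and the
gain SD to 2. It encodes the stated world of the signal-recovery
acceptance property ("strong fatigue-to-RPE coupling"): labels dominated by
fatigue progression rather than by who the subject happens to be. The
realistic default deliberately keeps more between-subject label variance,
which no force-derived feature can explain on held-out subjects.

### Repetition shape and fatigue decay

A repetition lasts `rep_duration_s`, drawn once per subject from the
protocol's 1-4 s range and reused across all reps and sets — the machine
enforces constant velocity over a fixed range of motion, so duration is a
subject constant. This is also what makes the generator's decay law exact:
with the shape fixed, per-rep work scales with the amplitude, and

work(set s) / work(set 1) = (1 - fatigue_rate)^(s - 1)

holds in closed form for noise-free traces (a frozen test asserts
0.95^6 for the default rate at set 7).

The noise-free shape is a fast linear rise to the peak over the first ~2%
of samples, an exponential settle (time constant 8% of the rep) onto a
plateau at `plateau_frac` of peak, and a brief terminal drop over the last
4%. The early peak mirrors the empirical observation that bench-press peak
force occurs in roughly the first 1-2% of the range of motion — which is
also why time-to-peak and rate of force development carry no fatigue trend
in this world (a property test checks the absence of a set-index trend).
Additive Gaussian noise has SD `noise_sd_frac x base peak x
(1 + variability_gain x (set - 1))`; after noise, samples beyond the rise
are capped at 97% of the rise maximum, so the early-peak constraint holds
for *any* noise level by construction, and samples are clamped at zero.
Repetitions are concatenated with ~0.5 s gaps of small positive noise
(never exact zero), so segmentation has real work to do.

### Labels

Latent fatigue of set s is 1 - E[work(s)]/E[work(1)]. The label is
`clip(round(intercept + gain x g(latent) + noise), 0, 10)` with label-noise
SD 0.5 by default — a small rounded Gaussian that reproduces a +/-1
disagreement band without modeling psychophysics. Three links g are
available:

* `"linear"` (default): g(x) = x;
* `"quadratic"`: g(x) = x^2 / 0.3, endpoint-matched to the linear link at
  x = 0.3. Over the latent range the 7-set protocol actually induces
  (0 to ~0.35) this is nearly linear in the extracted features, and a ridge
  model matches the tree ensembles on it — which is why it is *not* used as
  the "nonlinear cohort" in the acceptance suite;
* `"threshold"`: g(x) = 0.3 / (1 + exp(-(x - 0.15)/0.03)), a steep
  saturating link — exertion jumps once cumulative work loss crosses ~15%.
  This is the genuinely nonlinear world in which the tree models'
  advantage over ridge is expressed.

### What the simulator does not emulate

No eccentric phase (only the concentric push is generated, as in the
protocol it mirrors), no velocity or displacement signal, no
musculoskeletal or motor-control model, i.i.d. Gaussian force noise rather
than physiological tremor spectra, no intra-set fatigue within a
repetition, and label noise that is independent across sets rather than
auto-correlated. A green test therefore establishes that the *pipeline*
recovers the relationships the generator encodes — not that those
relationships hold in any particular human cohort.

## Preprocessing choices

**Zero-phase filtering.** The 4th-order Butterworth low-pass (20 Hz cutoff
at 50 Hz sampling) is applied forward-backward. Zero phase avoids the group
delay that would bias time-to-peak; the cost is a squared magnitude
response (the effective attenuation is |H|^2), which the tests account for
analytically: for the bilinear design with prewarping the single-pass power
response is exactly 1 / (1 + (tan(pi f/fs) / tan(pi fc/fs))^(2n)). Edge
transients are suppressed by odd-reflection padding of one warm-up length
(3 x filter order samples) with steady-state initial conditions, so a
constant trace passes through exactly; traces must be longer than the pad
and the error message names the minimum.

**Segmentation.** Onset is the first of k = 3 consecutive samples above
0.15 x trace max; offset the first of 3 consecutive samples below
0.10 x max after onset; segments shorter than 0.3 s are discarded.
Relative-to-max thresholds make segmentation invariant to uniform force
scaling (and hence to inter-subject strength differences); the hysteresis
gap (beta < alpha) prevents chatter around a single threshold. Windows are
half-open `[start, end)`; user-facing rep/set indices are 1-based.
Segmentation runs on the filtered, pre-normalization signal — normalization
is order-independent for relative thresholds, but fixing the contract keeps
artifacts comparable.

**Normalization.** Both plain per-mass (F/m) and allometric (F/m^0.67)
normalization are implemented; which fed the reference models is unstated
upstream, so the config selects one, defaulting to allometric. Raw force is
also available.

## Feature conventions

The printed formulas upstream mix moment conventions; the package resolves
them as: variance and SD use the N-1 (sample) divisor as printed; skewness
and kurtosis use 1/N central moments over the *population* SD, making them
the standard population moment ratios (kurtosis raw, not excess). The
moment identity rms^2 = mean^2 + variance (N-1)/N ties the conventions
together and is asserted at 1e-9 relative on every random repetition in the
acceptance suite. "Work" is the printed sum of force x sampling interval —
an impulse in N s; under isokinetic constant velocity it is proportional to
mechanical work, and no displacement signal exists to compute the latter.

Features are computed per repetition and aggregated per set (mean across
reps, except peak = max and work = sum): the upstream description is
ambiguous between repetition-level and set-level computation, and the
rep-then-aggregate choice keeps time-to-peak well defined. Constant
repetitions make skewness/kurtosis undefined; they are emitted as missing
and handled by the one imputation policy in the modeling stage, as are the
structurally missing previous-set relatives at set 1.

`delta_times_ratio` (the "delta x ratio" composite) is defined on work's
baseline-relative pair — work is the headline fatigue-sensitive feature —
and is configurable. The optional exponential family exp(f(s)/f(1)) is off
by default; no formula for it is stated upstream.

## Modeling choices

**Leak-free preprocessing.** Imputation medians, the |r| >= 0.5 Pearson
screen and standardization statistics are computed inside each training
fold. The single-pass variant described upstream (one preprocessing pass
over all data before cross-validation) leaks label information; it is
available behind `leak_free = FALSE` for comparison, but the honest
variant is the default.

**Regressors.** No tree-ensemble package is assumed: CART regression trees
with exact greedy splitting are implemented in compiled code, bagged with
bootstrap resampling for the random forest (400 trees, all features per
split — the scikit-learn regression default the reference configuration
names) and boosted with squared-loss gradients for the gradient-boosting
model (depth 6, 800 iterations, learning rate 0.04, minimum leaf 20). At a
few hundred rows, histogram binning is purely a speed optimization with no
methodological content, so exact splits are used. Ridge is solved in closed
form, (X'X + alpha I)^-1 X'y on standardized features with an unpenalized
intercept, matching the alpha = 1.0 convention of the reference
implementation. Tree models consume unstandardized features (they are
scale-invariant; blanket standardization would be cosmetic). All fits are
seeded through R's RNG and bit-reproducible.

**Cut-points.** Thresholds are midpoints between adjacent class medians of
the training predictions. When raw medians violate the label ordering,
adjacent classes are pooled by weighted pool-adjacent-violators first;
within a pooled block the degenerate internal boundaries are collapsed
toward the block edges so the block's region maps to its most frequent
class (ties to the lower class) — the minimal intervention that preserves
the median-midpoint idea while minimizing training misclassification.
Residual ties are separated by 1e-8 of the prediction range, so thresholds
are strictly increasing for every input. A prediction exactly on a
threshold goes to the lower class. The label range is discovered from the
data (any contiguous integer range, 0-10 or 1-10 alike), never hard-coded.

## Evaluation choices

Tolerance accuracies (|error| <= 0.5 and <= 1.0, inclusive) are computed on
the continuous predictions; exact accuracy and the confusion matrix on the
discretized ones; the report carries both paths explicitly because which
fed the published tolerance numbers is unstated. Consequently the ordering
"within +/-1 >= within +/-0.5" holds within the continuous path and
"within +/-1 (discrete) >= exact" within the discrete path, but a
cross-path comparison is not an invariant. R-squared and Pearson's r are
flagged `NA` (never silently zero) when the truth is constant, so
degenerate folds surface. Group K-fold assigns whole subjects to folds,
largest first onto the currently smallest fold with seeded tie-breaking; no
assignment rule is stated upstream, and balancing row counts keeps fold
metrics comparable. Bland-Altman limits use the sample (N-1) SD and
mean +/- 1.96 SD, with per-subject limits when groups are supplied.

## Reproducibility

Every pipeline stage derives its stream from the single top-level seed via
fixed substream offsets (cohort, model, CV), so changing the model seed
cannot perturb the cohort. `run_pipeline()` writes every artifact with an
MD5 checksum into the manifest; re-running a config reproduces identical
checksums, which the acceptance suite asserts byte-for-byte.

## Known limitations

Segmentation assumes gaps genuinely drop below 10% of the trace maximum;
back-to-back repetitions without force decay would merge. The generator's
fatigue is strictly geometric with no inter-set recovery, so
previous-set-relative features are less informative here than they may be
in real data. The forest's uniform-random bootstrap differs from
implementations that stratify; at these sample sizes the difference is
immaterial but seeds are not interchangeable across implementations. And
all acceptance evidence is conditional on the generator: external validity
requires real force-RPE data.
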