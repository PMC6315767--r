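---
title: "OPLS-DA biomarker discovery for untargeted faecal metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OPLS-DA biomarker discovery for untargeted faecal metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplsmark)
```

## The problem this package addresses

Untargeted LC-MS metabolomics of faecal extracts produces a table of a few
hundred putatively identified metabolite features over a few dozen samples.
In a typical case-control design — here, paediatric Crohn's disease patients
sampled before, during and after exclusive enteral nutrition (EEN)
treatment, against healthy controls — the analytical questions are: which
group pairs can be discriminated at all (and is the discrimination real
rather than overfit), and which individual metabolites carry that
discrimination reliably enough to be called biomarkers.

`oplsmark` implements this workflow end to end: pooled-QC quality
filtering, log2/Pareto pre-processing, OPLS-DA modelling with a three-part
validation (permutation testing, CV-ANOVA, an overfitting rule), a
multi-stage marker filtration cascade, and external-calibration
quantification of confirmed markers. A synthetic-data generator with
planted ground truth makes every stage testable without access to raw
instrument data.

## Pre-processing

**QC-RSD filter.** Pooled-QC injections (aliquots of all samples, injected
repeatedly through the run) measure technical precision per feature as the
relative standard deviation, `RSD = 100 * sd/mean` with the sample (n-1)
SD — appropriate for the small QC pool sizes (typically n = 5). Features
with QC RSD strictly above 30% (the conventional untargeted-metabolomics
cutoff) are removed, as are features whose QC RSD cannot be computed at
all: a feature whose precision cannot be certified is not interpretable
downstream.

**Missingness filter.** Features missing in strictly more than 20% of the
*biological* samples are removed; QC rows do not count. Both thresholds are
strict inequalities, so a feature at exactly the boundary is retained.

**Transform and scaling.** Intensities are log2-transformed (LC-MS peak
areas are approximately log-normal; the transform symmetrises them), after
zeros — non-detections, not true zeros — are converted to missing with a
warning. Pareto scaling then mean-centers each feature and divides by the
square root of its standard deviation. The quoted convention in
chemometrics software includes the centering even when only the division is
described, and the OPLS decomposition requires centered data, so
`pareto_scale()` always centers. A Pareto-scaled feature has variance
equal to its original SD — intermediate between no scaling (which lets
high-intensity features dominate) and unit-variance scaling (which
inflates noise features).

**Missing values at modelling time.** Filtering guarantees at most 20%
missingness per feature; the remaining holes are filled by half-minimum
imputation per feature (`impute_half_min()`), the conventional below-LOD
stand-in. Imputation keeps every cross-validation fold well-defined.
Univariate statistics in the marker cascade instead exclude missing values
pairwise, so a feature's p-value is never influenced by imputed values.

## The OPLS-DA model

For a two-class problem with centered matrix `X` (n samples x m features)
and class dummy `d` (plus/minus 1, centered), the orthogonal-projections
scheme iterates, for each of `n_ortho` orthogonal components:

    w  = X'd / |X'd|          candidate predictive direction
    t  = X w,  p = X't / t't  loading
    wo = p - (w'p) w          loading part orthogonal to w, normalised
    to = X wo, po = X'to/to'to
    X  = X - to po'           deflation

and finally extracts the predictive component `t[1] = X w` from the
deflated matrix, with y-loading `c = d't / t't`. Deflation makes
`X' to = 0`, so the predictive and orthogonal scores are orthogonal by
construction (asserted to 1e-8 in the tests). The decomposition is
complete: `X = t p' + sum(to po') + E` with
`|E|^2 = (1 - R2X(cum)) |X|^2` exactly. With `n_ortho = 0` the model
reduces to the first component of single-response PLS1, which is how it is
cross-checked against an independent implementation. There is no random
initialisation; the fit is deterministic, and the centered dummy coding
makes all results invariant to relabelling of the classes (up to the sign
of the scores).

The default `n_ortho = 1` reflects the 1 predictive + 1 orthogonal
structure typical of two-group metabolomics models of this size; it is a
plain argument everywhere.

**VIP.** Variable importance is normalised so that the mean squared VIP
over features is exactly 1 ("average importance = 1", making the
conventional `VIP > 1` cutoff meaningful). It is split into a predictive
part (from the predictive weights — between-group contribution; with a
single predictive component `VIPpred_j = sqrt(m) |w_j|`, so
`mean(VIPpred^2) = 1` identically), an orthogonal part (orthogonal weights
weighted by each orthogonal component's explained X-variation —
within-group contribution), and a total that weights both by their
explained sums of squares. Published VIP variants differ in the orthogonal
weighting; the formulation here is pinned by the identity tests, not by any
external table. A feature with `VIPortho > VIPpred` varies more within
groups than between them and is flagged `not_biomarker_relevant`.

## Model validation

**Cross-validated Q2.** `cross_validate()` uses K = 7 folds by default
(the convention of the commercial chemometrics software this workflow
mirrors), assigned round-robin in sample order — deterministic
reproducibility was preferred over randomised folds. The *entire* model,
including centering and orthogonal-component extraction, is refit on each
training partition; the held-out squared prediction errors accumulate into
PRESS and `Q2 = 1 - PRESS/SS_total`. Q2 can be negative (worse than
predicting the mean); on pure noise its mean is below zero, which the
acceptance battery checks.

**Permutation test** (999 shuffles by default): the labels are permuted,
the full cross-validated model refit, and (R2, Q2) recorded with the
absolute correlation between permuted and original dummies. The model
passes if the least-squares Q2-versus-correlation line (through the
permuted points plus the original at correlation 1) has intercept at or
below zero, or if no permuted Q2 reaches the original (a tie counts
against the model — the conservative reading).

**CV-ANOVA.** `F = ((SS_total - PRESS)/df1) / (PRESS/df2)` with `df1` the
number of fitted components (predictive + orthogonal) and
`df2 = n - df1 - 1`; p is the upper tail of `F(df1, df2)`. The named test
is defined only up to its degrees-of-freedom convention in the literature;
the component count is used here and is stated in the output. A negative
numerator clamps to `F = 0, p = 1`.

**Verdict.** A model is *valid* if the permutation test passes and
`R2 - Q2 <= 0.3` (larger gaps indicate overfitting), and *significant* if
additionally `p(CV-ANOVA) < 0.05`. Applied to the bundled table of 15
published pairwise model summaries, these two rules reproduce all 15
validity and all 15 significance labels exactly, and the recomputed
`R2 - Q2` column matches the printed one within rounding
(`tests/testthat/test-acceptance.R`).

## The marker filtration cascade

Stages, in fixed order, each recording the first failure per feature:

1. **t-test** on log2 values, keep `p <= 0.05`. Pooled-variance (Student)
   by default per the workflow's stated method; Welch available.
2. **Jack-knife CI**: the K cross-validation sub-model coefficient vectors
   are the jack-knife replicates;
   `SE = sqrt((K-1)/K * sum((b_k - mean(b))^2))` and the 95% interval is
   the full-model coefficient +- `t(0.975, K-1) * SE`. Features whose
   interval covers zero have unstable model contributions and are dropped.
   Reusing the CV folds makes the interval deterministic.
3. **BH q-value**, keep `q <= 0.05`. The q-values are computed across
   *all* features entering the cascade, not only the survivors of stages
   1–2: computing BH on an already-p-thresholded subset makes every
   q <= the threshold and the stage vacuous, so the full-set convention is
   the only self-consistent reading (it also makes the cascade monotone in
   its thresholds, which the tests assert).
4. **ROC AUC**, keep `>= 0.7`, with the conventional quality bands
   (0.9–1.0 excellent, 0.8–0.9 good, 0.7–0.8 fair, 0.6–0.7 poor, 0.5–0.6
   failed). The AUC equals the Mann–Whitney probability with ties counted
   half and is folded to `>= 0.5`, since a marker's quality is
   direction-agnostic (both depleted and enriched markers are reported).
5. **VIP**, keep `vip_total > 1`; `VIPortho > VIPpred` flags the feature
   as not biomarker-relevant. The flag does not drop by default — published
   marker tables of this workflow retain borderline features (VIP totals
   of 0.99 and 0.89) — but `cascade_config(require_pred_ge_ortho = TRUE)`
   enforces it.
6. **Q-Q normality** of the pooled log2 values: R2 of the ordered sample
   against normal quantiles at plotting positions `(i - 0.5)/n`, with
   `is_normal = r2 >= 0.95`. The 0.95 cutoff is this package's choice (the
   workflow's source reports pass/fail but no threshold). Recorded, not
   enforced by default (`enforce_qq = TRUE` enforces): heavily censored
   markers can fail normality while remaining biologically real, and the
   flag lets the analyst decide whether to report the parametric p-value.

Survivors are ranked by total VIP, descending. Fold changes are reported
as raw-scale group-mean ratios with their log2.

## Quantification

External calibration: an OLS line `response = slope * conc + intercept`
over standards (for the bundled fatty-acid example, 0.1–16 ug/mL), inverse
prediction `conc = (response - intercept)/slope`, then conversion to ug per
g of dry faeces via `conc * extract_volume_ml * dilution_factor /
dry_mass_g`. The conversion factors are explicit arguments because
extraction volumes per gram are protocol-specific. Predictions outside the
calibration range — including negative ones — are flagged, never clipped.
Group tables report mean, sample SD and `SEM = SD/sqrt(n)`.

**Calibration of the group-comparison test.** The bundled fatty-acid
dataset prints group-comparison p-values of 0.019 and 0.046 with a
footnote stating a log2 basis. Recomputing from the printed per-sample
concentrations: no log2-scale t-test reproduces them (pooled log2 gives
0.0020 and 5.5e-5; Welch log2 gives 0.0034 and 5.6e-5), while **Welch's
t-test on the raw concentrations gives 0.0188 and 0.0456** — matching both
printed values to the printed precision (and matching the behaviour of a
spreadsheet two-sample unequal-variance TTEST on the raw columns). The
package therefore keeps `compare_groups()` defaulting to the *stated*
method (log2, pooled) and documents `log2 = FALSE, var_equal = FALSE` as
the calibrated variant that reproduces the printed table; the acceptance
checks use the calibrated variant and this discrepancy is deliberately
surfaced rather than hidden. Two further printed values differ in their
last digit from recomputation (a group SEM pair and one group mean),
consistent with the printed per-sample values having been rounded before
the summary row was computed; the tests use last-digit tolerances there.

## The synthetic-data generator

`synthetic_config()` defaults emulate the motivating study design: six
groups (HC and five patient timepoints PA–PE) of 11/11/10/11/11/11
biological samples, 600 features, five pooled-QC injections, and eight
differential features in the PA-analogue group whose planted fold changes
(0.15–20.3) are the published case/control ratios.

* **Intensity model**: log-normal — per-feature baseline log2 mean drawn
  from U(10, 24) (the span of LC-MS peak-area magnitudes), biological
  noise N(0, 1) on the log2 scale. An SD of 1 log2 unit (two-fold typical
  biological spread) is a realistic figure for faecal metabolite
  intensities, where inter-individual variation is large.
* **Group effects** are multiplicative (additive on log2), one affected
  group per planted feature for unambiguous ground truth.
* **QC noise** is multiplicative log-normal with
  `sigma = sqrt(log(1 + cv^2))` and mean correction `-sigma^2/2`, so the
  QC coefficient of variation equals the requested RSD exactly and a zero
  RSD reproduces the biological means bit-for-bit. The default 14% is the
  motivating study's measured pooled-QC RSD.
* **Missingness**: 1% MCAR plus per-feature censoring of the lowest 2% of
  observed values. The mechanism (intensity-dependent dropout) is the
  LC-MS-realistic part; the rates are free parameters — the motivating
  study reports having missing values but not how many — chosen small
  enough that the 20% missingness filter rarely fires at defaults.

What the generator does *not* emulate: retention-time drift, batch
effects, correlated metabolite blocks (features are independent given
their group), non-Gaussian heavy tails, and structured (informative)
missingness beyond the low-intensity censoring. Passing the recovery tests
therefore certifies the statistical machinery, not robustness to every
real-data pathology.

## Numerical choices and degenerate inputs

* All decompositions are plain dense linear algebra; no iterative
  convergence is involved beyond the (single-response, one-step) NIPALS
  scheme, so there are no tolerance knobs in the fit itself. Orthogonal
  extraction stops early if the orthogonal loading norm falls below 1e-10
  (no orthogonal variation left).
* Round-robin CV folds are deterministic; a training fold reduced to a
  single class is an error, not a silent reassignment.
* Degenerate t-tests (zero variance in both groups) return p = 1 for
  equal means; zero-SD features are an error in `pareto_scale()` (with
  the offending features listed) and in `qq_normality()`.
* Ties in the AUC count one half; a permuted Q2 exactly equal to the
  original counts as exceeding it (conservative).
* The permutation count is exactly `n_perm` (default 999) and the whole
  validation stage is reproducible from one seed; `run_pipeline()`
  derives per-stage seeds by hashing the stage name into an offset, so
  stages are decoupled but jointly reproducible.

## Problem sizes used in the tests

The test-suite and acceptance battery run at desk scale, chosen as the
smallest sizes at which every behaviour under test is comfortably
identifiable: 20 x 50 matrices for the PLS1 oracle comparisons; 100
features / 11 + 11 samples with ten planted 16-fold markers and 10% QC RSD
for parameter recovery (20 seeds, 199 permutations, with the 999 default
exercised once); 100 seeds for the null calibrations. Under those
recovery conditions the cascade recovers ~9 of 10 planted markers on
average. One caveat is reported honestly: with 100 features and 22
samples, R2Y saturates near 0.99 while Q2 centres on ~0.75, so the
R2 − Q2 gap centres on 0.24 and crosses the 0.3 overfit rule in roughly
one seed in ten — the validity verdict for the planted-effect model is
therefore seed-dependent in about that fraction of runs, which is a
property of the overfit rule at this sample-to-feature ratio, not of the
planted signal.

## Known limitations

* Two-class models only; multi-group designs are analysed pairwise, as in
  the motivating workflow.
* One predictive component; multi-component OPLS-DA (multi-class Y) is out
  of scope.
* No normalisation to total intensity or internal standards, no batch
  correction, and no raw spectral processing — the package starts from a
  feature table.
* The CV-ANOVA degrees of freedom follow the component-count convention;
  other software may use slightly different conventions, so p-values are
  comparable within this package rather than across packages.
* Jack-knife intervals reuse the Q2 cross-validation folds; with K = 7
  they are coarse (6 df), which is the price of determinism.
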