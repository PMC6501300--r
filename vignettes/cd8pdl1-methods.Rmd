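---
title: "Methods: the CD8xPD-L1 signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CD8xPD-L1 signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Manual PD-L1 tumor-cell scoring is an imperfect selector of NSCLC patients
for anti-PD-L1 therapy: many scored-positive patients do not respond, and
some scored-negative patients do. A biomarker that combines the tumor's
target expression (PD-L1+ cell density) with evidence of an existing
cytotoxic infiltrate (CD8+ TIL density) should be a better predictor of
response to checkpoint blockade than either alone. The combination studied
here is the simplest one:

    score = CD8+ density (cells/mm2) x PD-L1+ density (cells/mm2)

in the pathologist-annotated tumor region, in cells^2/mm^4, dichotomized
at a cutoff learned on a training cohort. `cd8pdl1` implements every stage
of that analysis — image quantification, cutoff learning, survival
evaluation, cohort transfer — plus a synthetic-data module that generates
cohorts and images with known ground truth, so the entire pipeline is
testable without access to clinical data.

## Image quantification

Chromogenic IHC images are quantified in three steps.

1. **Optical density.** Stain absorbances add in OD space
   (Beer-Lambert), not in intensity space, so the 8-bit RGB image is
   transformed per channel as `OD = -log10((I + eps)/I0)` with
   `I0 = 255` and `eps = 1/255` guarding `I = 0`. Negative OD
   (intensities above background) is clipped to 0. Quantization limits
   the transform's fidelity: a half-count error at intensity `I` moves OD
   by `0.434 * 0.5 / I`, which stays below 0.02 for OD up to about 1.3
   and grows to roughly 0.085 at OD 2. Thresholds used downstream sit
   well inside the reliable range.
2. **Stain unmixing.** Each pixel's OD vector is expressed in a basis of
   unit stain vectors (hematoxylin, DAB, and a residual direction
   completing the basis) by a linear solve — classical color
   deconvolution. The default vectors are the widely used
   hematoxylin/DAB directions; a calibrated 3x3 matrix can be supplied
   via CSV (`read_stain_matrix()`). Negative concentrations, which arise
   from noise, are clipped to 0. A condition-number check rejects
   near-singular matrices.
3. **Detection and density.** The DAB concentration map is binarized at a
   threshold (default 0.3 OD), 8-connected components are labeled, and
   components with pixel area in `[20, 2000]` are kept. A cell is counted
   if its centroid falls inside the tumor mask (an unambiguous rule for
   boundary-straddling objects), and density is the in-mask count divided
   by mask area, `n_pixels * (microns_per_pixel/1000)^2` mm2.

Connected-component labeling is done by iterative minimum-label
propagation over the 8-neighborhood. Touching cells are not split (no
watershed); the synthetic generator guarantees separation, and on real
tissue this is a documented simplification — clustered infiltrates would
be under-counted.

## Cutoff learning

The cutoff for each measure is chosen on the training cohort by
maximizing the positive predictive value (PPV): the fraction of
responders (complete or partial response, RECIST v1.1) among
score-positive patients, equivalently the ORR in the positive subgroup.
Unconstrained PPV maximization degenerates into tiny positive groups, so
two constraints are enforced at every candidate:

* two-group log-rank p-values for both OS and PFS at or below 0.05, and
* signature-positive prevalence between 30% and 70%.

The candidate grid is the set of observed unique scores: with the
">= cutoff is positive" rule, prevalence, PPV and the log-rank statistics
only change when the cutoff crosses an observed value, so the grid is
exhaustive and the search is an exact enumeration, not a heuristic. Ties
in PPV are broken by smaller OS p-value, then smaller cutoff (the
tie-break is this package's rule; any deterministic rule would do). PPV
intervals are exact binomial (Clopper-Pearson via beta quantiles). With
no feasible candidate the search reports an absent best rather than
relaxing a constraint — at a training size of 84 this happens on a
minority of simulated replicates and is a legitimate outcome of the
procedure.

The signature, CD8 and PD-L1 cutoffs are each optimized independently on
their own score column; the signature cutoff is *not* the product of the
component cutoffs (the published values 297 x 644 = 191268 exceed the
published signature cutoff 1.54e5).

## Survival machinery

Kaplan-Meier estimation, Greenwood variance with log-log confidence
bands, the two-group log-rank test, and Cox partial-likelihood fits
(Efron tie handling by default, Breslow optional) are delegated to the
`survival` package; this package defines the surfaces the analysis needs
and adds what `survival` does not provide directly. The median is
reported as the first event time at which the survival estimate is at or
below 0.5 (a curve that touches 0.5 exactly has its median at that time,
not at the plateau midpoint), with an "NR" (not reached) sentinel when
the curve never falls that far; its CI inverts the log-log band
(Brookmeyer-Crowley). Nested Cox models are compared by the
partial-likelihood ratio chi-square — this is what an "analysis of
variance" of nested proportional-hazards fits computes — with df equal to
the parameter-count difference; identical models give df 0 and p 1.
Report tables band p-values as `-` (> 0.05), `+` (<= 0.05), `++`
(<= 0.005), `+++` (<= 0.0005), boundaries inclusive.

Categorical covariates are one-hot encoded against their first factor
level; positive/negative label columns become 0/1 indicators with
negative as reference. Age and prior therapy lines enter the Cox model as
continuous/ordinal values (they are binned only for split balancing).
Perfect separation or non-convergence is flagged on the fit rather than
raised, so report generation can propagate flagged rows.

## Cohort transfer

Positivity is transferred to an independent cohort without re-optimizing:
the target cohort is ranked by score and the top `q` fraction labeled
positive, where `q` is the reference cohort's positive prevalence carried
at full precision. `n_positive = round(q * n)` (floor/ceiling options
exist; the choice moves the result by at most one patient). The derived
cutoff is the smallest positive score; boundary ties are resolved by
stable input order with a warning.

## The stratified split

The treated cohort is split into training and test sets balanced on
manual PD-L1 status (>= 25%), response, prior therapy lines, stage and
gender: within each joint stratum of those variables, patients are
allocated proportionally with largest-remainder rounding (so the global
train size is exact) and shuffled under the supplied seed. Numeric
balance variables with many levels are binned into tertiles for
stratification only.

## What the synthetic generator emulates

`generate_cohort()` draws, per patient:

* **Densities**: bivariate log-normal on the log scale — CD8 median 200
  cells/mm2 (sdlog 1.0), PD-L1 median 300 cells/mm2 (sdlog 1.1),
  correlation 0.4. Log-normality is a modeling choice (non-negative,
  right-skewed, simple correlation control); the source study reports no
  distributional form.
* **Response**: Bernoulli with `logit p = logit(0.10) + 1.2 z`, where `z`
  is the standardized log signature. The intercept and slope were set so
  the positive subgroup's ORR lands near 0.3-0.4 against roughly 0.06 in
  the negative subgroup, matching the contrast reported for the clinical
  training and test sets (PPV 0.42/0.36 vs 0.09/0.07).
* **Survival**: exponential proportional hazards. The linear predictor
  uses a signature-high indicator (log score above the cohort median) and
  liver metastasis. Defaults: baseline median OS 9 months
  (hazard ln2/9), PFS 2.5 months, signature log-HR `log(7.8/21)` (the
  ratio of the reported signature-negative to signature-positive median
  OS, about HR 0.37), liver-metastasis log-HR `log(2.5)`. Latent PFS is
  capped at latent OS before censoring, so progression never postdates
  death. Censoring is independent exponential (0.03/month), giving about
  60% OS events at n = 163 — comparable to the 98/163 reported.
  An indicator (rather than the continuous z) drives the hazard so that a
  Cox fit of the median-split indicator recovers the configured log-HR
  exactly; with a continuous generator no dichotomized fit has that
  property.
* **Covariates**: histology, smoking status, gender, stage, liver
  metastasis and prior lines from configurable category prevalences
  typical of advanced-NSCLC trials; age normal(64, 9) truncated to
  [30, 90]. Only the signature indicator and liver metastasis carry
  survival effects.
* **Manual PD-L1 TC%**: a logistic transform of log PD-L1 density with
  reader noise (sd 0.5 on the logit scale), so the manual and digital
  measures correlate without being interchangeable.

The non-ICT control cohort in the analysis scripts uses the same
generator with the signature log-HR set to 0 (the signature is treated as
predictive of checkpoint-therapy benefit, not prognostic), a surgical
baseline median OS of 48 months and lighter censoring.

`generate_ihc_image()` composites DAB disks over a uniform hematoxylin
background in OD space and converts to 8-bit RGB with additive Gaussian
OD noise (default sd 0.02), so the quantification model is exact up to
noise and quantization. Cell placement is rejection sampling with a
minimum separation of one diameter plus 2 px; impossible placements fail
with a bounded-retry error.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: nuclear texture and stain heterogeneity,
touching/overlapping cells, section and scanner artifacts, dual-stain
chemistry, a CD8-specific prognostic effect in the control cohort,
non-proportional hazards, informative censoring, and any real-world
relationship between image content and patient outcome (cohort tables
and images are generated independently).

## Numerical choices and degenerate inputs

* All stochastic functions take an explicit integer seed and touch no
  global RNG state (`withr::with_seed`).
* Dichotomization is `>= cutoff` everywhere, mirroring the ">= 25%"
  convention of manual scoring; at exact-tie scores results can shift by
  one patient relative to a strict `>` rule.
* An empty mask, an all-identical score vector, a zero-event log-rank,
  or a non-nested model comparison raise immediate validation errors
  naming the offending input; an empty detection map returns zero
  detections (not an error); an empty positive group makes a cutoff
  infeasible with the reason recorded.
* Scores are kept at full floating precision in cells^2/mm^4; rounding
  (prevalence and PPV to 2 dp, medians to 1 dp) happens only in display.

## Problem sizes used in the checks

The test suite validates the statistical machinery at the sizes where its
oracles are sharp: distributional checks and response-rate recovery at
n = 5000; Cox and KM parameter recovery at n = 2000; log-rank type-I
error over 2000 null simulations of 40 + 40 patients; nested-LR null
calibration over 1000 replicates at n = 100; brute-force equivalence of
the cutoff search over 20 seeded cohorts up to n = 100; and image
recovery over a 3x3 grid of cell count x noise at 512 x 512 px. The
analysis drivers use the study-scale sizes (163 treated, 199 control,
84/79 split).

## Known limitations

* Detection is threshold + connected components + area filter — a
  deliberate, oracle-testable simplification of proprietary rule-based /
  machine-learned segmentation; it is not expected to match a production
  segmenter on real tissue.
* Exponential baselines make medians analytic but cannot represent
  changing hazards; the evaluation machinery itself (KM, log-rank, Cox)
  does not depend on that assumption.
* The transfer step assumes score ranks are comparable across cohorts;
  staining-platform calibration is out of scope.
* Confidence-interval conventions (log-log KM bands, Clopper-Pearson
  PPV) are stated choices; other conventions give slightly different
  intervals.
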