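---
title: "Early prediction of canine CKD: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early prediction of canine CKD: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ckdwatch)
```

This vignette is the package's own account of the science it implements:
the labeling and evaluation rules, the recurrent classifier, the
synthetic-data generator that stands in for clinical records, and the
places where the design was genuinely open and a choice had to be made.

## The problem and the modeling frame

Canine chronic kidney disease (CKD) is typically diagnosed once azotemia
is overt; the question this pipeline addresses is how much earlier a
diagnosis could be flagged from data that primary-care practices already
collect: serum creatinine, blood urea nitrogen (BUN), urine specific
gravity (USG), urine protein, body weight, and age. The unit of analysis
is one dog's age-ordered visit sequence. Time is fractional age in years
everywhere — calendar dates never enter — and all windows are arithmetic
on age (30 days = 30/365.25 y). Missing values are explicit (`NA`); zero
is never a missing-value sentinel.

## Labeling rules and the evaluation age T0

Every record receives exactly one status:

* **CKD** — any visit carries a diagnosis code from the configured set
  (default `"CKD"`). T0 is the age at the *first* diagnosed visit:
  diagnoses may be re-entered at later visits, and anchoring at the first
  occurrence is the only choice that makes the "time before diagnosis"
  horizon well defined. Data more than 30 days after T0 are discarded
  (the window exists to catch lab results filed shortly after the
  diagnosis visit, not to extend the history).
* **PROBABLE_CKD** — no diagnosis code, but a structured risk token
  (`"CKD_RISK"`) or at least two *distinct* CKD-suggesting criteria
  anywhere in the record: creatinine above the catalog normal high, USG
  below the catalog normal low, or a note token from the lexicon
  (`"CKD"`, `"azotemic"`, the two renal-diet product names), matched
  case-insensitively and exactly at token level. Whether "two data
  points" means two distinct criteria or any two qualifying measurements
  is ambiguous; the distinct-criteria reading is the default because a
  single transiently azotemic dog re-measured twice is weaker evidence
  than azotemia *plus* dilute urine, and the alternative reading is one
  configuration switch away (`count_mode`).
* **NO_CKD** — the healthy label must be validated by follow-up: records
  qualify only when their visits span at least 2 disease-free years, T0
  is set to the last visit age minus 2, and those final 2 years are
  removed from the usable data. A span shorter than the lookahead cannot
  validate the label and the record is **EXCLUDED** (a value, never an
  error).

Probable records are labeled, counted, and then quarantined: they enter
neither training nor sensitivity/specificity. `build_sequences()` refuses
them at the type level.

## Cohort filtering

Laboratory values more than 6 population standard deviations above the
top of the normal range are set to missing before anything else; the SD
is computed from the cohort's observed values per analyte (and is
overridable). The rule is deliberately one-sided — implausible low values
of the modeled analytes are already bounded by physiologic floors, and a
symmetric rule would mask genuine disease signal in a strongly
right-skewed quantity such as urine protein.

Pre-T0 visits with neither a blood nor a urine result are dropped ("had
no laboratory analysis" is read as *neither*, not *not both*: with ~60%
urinalysis missingness the conjunctive reading would discard most of the
cohort). A record is then eligible iff the 4 years up to T0 contain at
least 2 visits, of which strictly more than 50% carry a blood result and
strictly more than 25% a urine result — per-visit presence fractions, not
per-cell completeness. Thresholds honour the wording literally: "at
least" is `>=`, "more than" is `>` (a record with urine at exactly 1/4 of
in-window visits is rejected).

## Truncation augmentation

For each training record with $n$ usable visits, copies with the last
$k = 1 \dots n-1$ visits removed are added, keeping a copy only when the
gap between its new last visit and T0 is at most 2 years. This enriches
training with records that *stop* well before diagnosis — exactly the
situation an early-warning model faces at deployment. Copies keep the
label and T0 and carry provenance (origin id, $k$). Healthy records are
augmented too: the source procedure applies augmentation to "the original
records" without restriction, and augmenting one class only would teach
the net that short sequences mean disease. Augmentation is never applied
to the test set.

## Imputation

Missing blood/urine values are filled by a chained nonparametric scheme
in the spirit of missForest: initialise missing cells at column means,
then sweep the analytes in order of ascending missingness, regressing
each on all others (random forest, 50 trees, seeded per column) over the
current completed matrix and updating that analyte's missing cells.
Sweeps stop when the normalized change in imputed values drops below
`tol = 1e-3`, when it starts increasing again (the usual chained-
imputation stopping heuristic), or at `max_iter = 10`. A `"linear"`
method (chained `lm`) exists for contexts where imputation quality is not
the object of study.

Two leak-prevention choices are deliberate. The imputer's input matrix
contains analyte columns only — status, T0 and diagnosis codes are not
part of its signature, so the "imputation never sees the outcome"
property holds by construction. And the imputer is fitted on the
*training* partition only, then applied to both partitions; whether the
original workflow imputed before or after splitting is unstated, and the
leak-free order is the defensible default (`impute_before_split = TRUE`
restores the other convention). Observed cells are preserved exactly;
imputed USG is clipped to the physiologic range [1.001, 1.065] and other
analytes to non-negative values.

Weight and age are not imputed: age is always present, and missing weight
is carried forward from the most recent prior visit (falling back to the
cohort median) when sequences are assembled — a clinically natural rule
for a slowly varying covariate.

## The recurrent classifier

The network is a stack of Elman-style recurrent tanh layers over the
standardised per-visit feature vector, with a 2-unit softmax head read at
the final visit; $p(\mathrm{CKD})$ is the first component:

$$ h^{(l)}_t = \tanh\!\big(W^{(l)} x^{(l)}_t + U^{(l)} h^{(l)}_{t-1} + b^{(l)}\big), \qquad
   p = \mathrm{softmax}\big(W^{o} h^{(L)}_T + b^{o}\big). $$

Defaults follow the selected production configuration: hidden widths
5-3-3, 8 training epochs, 20% dropout. Design and numerical choices:

* **Training** minimises final-step cross-entropy by backpropagation
  through time with per-parameter RMSprop (decay 0.9, $\epsilon=10^{-8}$).
  Learning rate (`1e-3`) and decay are not externally fixed anywhere, so
  they are configuration-exposed defaults.
* **Sequences are processed unpadded, one at a time**; `batch_size`
  controls how many sequence gradients are averaged per update and
  defaults to 1 (pure per-sequence updates). Results are independent of
  batch composition up to floating-point association.
* **Dropout** is inverted dropout on hidden activations as they feed
  *upward* (to the next layer and the output head), resampled per time
  step; the recurrent path is not dropped, which keeps the hidden state
  dynamics intact — the standard way to regularise stacked recurrent
  nets without destroying memory.
* **Age is a per-visit feature**, so truncated training copies naturally
  look "younger"; supplying age only at T0 would contradict truncation
  augmentation.
* **Initialisation** is uniform scaled by fan-in, fixed by the seed;
  training is bit-reproducible given the configuration.
* **Correctness oracle**: the analytic BPTT gradients are checked against
  central finite differences (relative error ≤ 1e-4) on tiny nets — this,
  not any fit statistic, is the core correctness test of the
  implementation.

Feature selection uses the greedy bottom-up and top-down wrapper with a
two-hidden-layer 3-7 selection net: each candidate subset is scored by
mean fold F1 at the 0.5 cutoff under stratified cross-validation after
retraining from scratch. The hybrid metric name used for this step in the
source workflow ("F1 cross-entropy") is not defined anywhere; training
with cross-entropy and scoring folds by F1 is the reading implemented
(the alternative — a differentiable soft-F1 training loss — is noted but
not the default). The architecture screen scores a configurable grid by
cross-validated F1 (default 10 folds) and breaks ties toward fewer
parameters.

## Evaluation

At the 0.5 cutoff (ties classify as CKD), the at-diagnosis summary is
computed over test records with a usable visit within 3 months of T0.
Confidence intervals are Wald intervals with the exact quantile 1.959964
(a `rounded_z` flag restores the conventional 1.96), clipped to [0, 1].
PPV and NPV are prevalence-adjusted with the population prevalence 0.83%
by default, never the sample mix — at realistic prevalence a PPV in the
tens of percent coexists with NPV above 99%, which is why the negative
prediction is the clinically reliable one.

Horizon evaluation truncates each CKD record to visits at least $h$ years
before T0 and recomputes sensitivity; records emptied by truncation drop
out of that horizon's denominator (a `count_as_missed` mode scores them
as misses instead). Specificity always comes from untruncated healthy
records: their T0 is an accounting construct (last visit minus the
validation window), so a "trajectory toward T0" has no clinical meaning
for them, and their specificity is better examined by age via the
stratified report. Life-stage strata are adult [1.5, 6.5), mature
[6.5, 9.75), senior [9.75, 13), geriatric [13, ∞), with boundary ages
assigned to the older stage.

## The synthetic-EHR generator

The generator defines the study conditions for everything downstream. It
emulates:

* two latent groups with analyte/weight/age moments at T0 matching the
  study-population summary (CKD: creatinine 2.67 (1.86) mg/dL, BUN 56.23
  (32.72) mg/dL, USG 1.020 (0.011), urine protein 91.01 (180.81) mg/dL,
  age 11.56 (3.37) y, weight 13.04 (11.20) kg, ~15.2 visits; healthy:
  1.09 (0.29), 17.38 (5.59), 1.039 (0.012), 49.52 (136.21), 7.19 (2.93),
  15.10 (12.42), ~12.0 visits);
* a **linear disease trajectory**: for CKD dogs each modeled analyte's
  expectation moves linearly from the healthy mean to the CKD T0 mean
  over the 2-year progression window (creatinine, BUN and urine protein
  rise; USG and weight fall). Only endpoint moments are known; linear
  interpolation is the minimal trajectory assumption and
  `trajectory_mean()` exposes the closed form;
* **censored-Gaussian noise with moment-matched location**: values are
  Gaussian with the group SD, floored at a physiologic bound (0 for
  non-negative analytes, 1.001 for USG). Because several targets put
  substantial Gaussian mass below the floor (urine protein's SD is twice
  its mean), naive censoring would bias group means upward; the
  generator therefore shifts the pre-censoring location so that the
  *post-censoring* expectation equals the target, inverting
  $E[\max(X, c)] = c + \sigma\,g((\mu - c)/\sigma)$,
  $g(m) = m\Phi(m) + \phi(m)$, on a cached grid. Group-mean recovery is
  then exact in expectation, which is what the 3-standard-error
  calibration test checks at 5,000 dogs per group;
* **block urinalysis missingness**: one Bernoulli per visit (default
  0.60) masks the whole urine panel, reproducing the observation that
  urinalysis simply is not run at most visits, against ~10% independent
  missingness for blood analytes;
* visit gaps exponential with mean 0.5 y; diagnosis-age and last-visit
  anchors drawn from the group age distributions; weight modeled with a
  dog-level baseline plus disease drift and small per-visit jitter (an
  i.i.d. weight would bounce tens of kilograms between visits while
  keeping the right cross-section);
* probable-CKD dogs: healthy trajectories with at least two injected
  CKD-suggesting signals and no diagnosis code; the 35-analyte catalog's
  remaining analytes as stationary mid-range noise in both groups.

What it deliberately does **not** emulate: cross-analyte correlation
beyond the shared trajectory mean (analytes are independent given the
mean), breed effects, comorbidities that mimic CKD in old dogs (nuclear
sclerosis, osteoarthritis), seasonal patterns, or realistic hematology
dynamics. Consequently, passing tests demonstrate that the pipeline's
machinery is correct and well calibrated under these conditions — not
that the reported operating characteristics transfer to clinical data.

## What the synthetic replica does and does not reproduce

On the default 500 + 500 cohort the trained default net separates the
held-out classes almost perfectly in rank terms (AUC ≈ 0.99) and its
horizon sensitivity decays monotonically, qualitatively matching the
published early-detection profile. The fixed 0.5-cutoff specificity,
however, sits below what a large balanced clinical test set yields,
for a structural reason worth stating: the eligibility filter removes
roughly 45% of healthy dogs (the strict urine-fraction rule colliding
with 60% urinalysis missingness and shorter healthy histories), so the
training mix is CKD-heavy, and age is a genuinely informative feature —
old healthy dogs are rare in training and attract false positives. This
is the same age-driven specificity loss the source workflow reports in
its oldest stratum, amplified by the small synthetic healthy test group
(a few dozen eligible dogs, so each false positive costs percentage
points). The package's performance tests therefore check the
discrimination properties (AUC, an operating point with sensitivity
> 0.8 at specificity > 0.9, and 0.5-cutoff sensitivity), and the
stratified report is the tool for inspecting the age trade-off.

## Problem sizes and seeds

The bundled analyses and tests choose sizes that keep a complete run on a
single CPU in minutes: 500 + 500 (+ 50 probable) dogs for the study
replica, 5,000 per group for generator calibration, 60-dog cohorts with a
3-7 selection net and 3 folds for the wrapper-selection demonstration,
and a reduced architecture grid. The full-scale searches (1–5 layers,
3–200 nodes, 10 folds) remain reachable through configuration. One global
seed drives everything; per-stage seeds are derived by a fixed affine
hash (`stage_seed()`), so any stage can be rerun in isolation.

## Known limitations

* Prevalence enters PPV/NPV as an external constant; it is itself an
  estimate, and predictive values move substantially within its
  plausible range.
* The Wald interval is used as specified; it degenerates at rates of 0
  or 1 (zero width after clipping) where a score interval would not.
* The imputer provides single imputations only; no uncertainty
  propagation.
* The generator's independence and linearity assumptions make the
  synthetic classification problem easier in rank terms than clinical
  data; absolute synthetic sensitivities at long horizons should not be
  read as clinical estimates.
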