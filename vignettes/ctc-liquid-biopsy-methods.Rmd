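---
title: "Methods: CTC panel scoring, time-dependent survival models, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTC panel scoring, time-dependent survival models, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcdx)
```

## The measurement model

Bulk qRT-PCR of CTC-enriched blood fractions yields one cycle threshold
(Ct) per gene and sample. `ctcdx` works on the inverted scale,
*expression* = `ct_max − Ct` with `ct_max = 40` cycles, so expression lives
in `[0, 40]` expression units and an undetected well (no amplification by
cycle 40) scores exactly 0. Undetected wells are *encoded* as Ct = 40; a
well physically missing from a plate is filled in as undetected and logged
per sample, and samples missing more than 25% of panel wells are flagged
and excluded from score computations (the threshold is a package choice; a
quarter of a 22-gene panel is where imputation starts to dominate any
score).

Expression is deliberately **not** housekeeping-normalised before
thresholding. Because patient and healthy-donor (HD) samples are processed
identically and compared gene-by-gene against HD levels from the same
assay, the HD calibration already absorbs assay-level offsets; and raw
`40 − Ct` keeps the EM-score boundary statements exact (a detected gene
always contributes positive signal). A ΔCt mode could be layered on top of
the same interface if plate effects were a concern; we document the choice
rather than hide it.

### HD positivity thresholds

For every gene and processing arm (with / without red-blood-cell lysis,
which changes background), the threshold is the mean plus one *sample*
standard deviation (divisor n − 1; the HD arms are small, 54/55 samples at
the default conditions) of HD expression. A gene is *positive* when its
expression is strictly above the threshold — a value exactly at the
threshold is negative. Under an approximately normal HD background this
calls about the upper one-SD tail (≈ 15.9%) of fresh HD samples positive
per gene, which the test suite checks by simulation at n = 500 per arm.

### The EM score

Four mesenchymal/stem genes (*ALDH1A1*, *CDH2*, *FN1*, *ZEB2*) and four
epithelial genes (*CDH1*, *EPCAM*, *KRT7*, *KRT18*) define

$$EM = \frac{\sum_{mes}(40 - Ct) - \sum_{epi}(40 - Ct)}
            {\sum_{all\,8}(40 - Ct)} \in [-1, +1].$$

The denominator is the sum over all 8 genes, which makes the two boundary
statements exact: +1 when only mesenchymal/stem genes are detected, −1 when
only epithelial genes are detected. When no EM gene is detected the score
is 0/0; we return it as undefined (`NA`) and exclude such samples from EM
analyses rather than coercing to 0, since "no tumor signal" carries no
polarity information. Genes of ambiguous polarity (e.g. *FGFR1*, *MUC1*,
*EGFR*) are not part of the 4+4 sets. The score is antisymmetric under
swapping the two sets and invariant to a common positive scaling of the 8
expression levels; both are verified as property tests.

## Counts and endpoints

CTC counts are per blood tube (~9.5 mL); no per-mL normalisation is
applied. Counts above 40 are truncated to 40 *only* where the count enters
a model as a continuous covariate; raw counts are kept everywhere else.
Dichotomization uses count ≥ cutoff (inclusive), default cutoff 5.

Time is measured in months from enrollment consent. A patient who dies
without documented progression is counted as having progressed on the date
of death, for first-progression and recurrent-event analyses alike.

Per-visit prognostic models use a **landmark** convention: survival is
measured from the visit's sample time among patients still event-free and
under follow-up then. The alternative — keeping enrollment as the origin —
credits post-visit survival to a pre-visit covariate and introduces
immortal-time bias, so landmarking is the package default and the choice is
surfaced in the function documentation.

## Survival machinery

* `km_fit()`: product-limit estimate, Greenwood variance, log-log
  confidence intervals; the median is the first time the curve reaches 0.5
  or below.
* `cox_fit()`: Breslow partial likelihood maximised by Newton–Raphson (via
  the `survival` package, convergence tolerance 1e-9, up to 100
  iterations), Breslow ties by default to match the conventions of the
  field's dominant software; Efron ties available. Robust sandwich variance
  clustered on patient whenever requested; Wald intervals at 95%.
  Monotone-likelihood (separation) and singular fits are reported as
  errors naming the covariate rather than returned as huge coefficients.
  The test suite cross-checks the maximiser against an independent
  grid-search maximisation of a hand-written Breslow partial likelihood.
* `build_counting_process()`: splits follow-up at covariate measurement
  times with last-value-carried-forward covariates. A measurement applies
  from its own time forward; the interval before the first measurement uses
  that baseline measurement (visit 1 is essentially at consent). A
  covariate measured exactly at an event time takes effect just *after* it.
  In recurrent mode the split adds every progression event on the total
  time scale and each row carries an event-number stratum (1 + prior
  events). The continuous count column is truncated at 40 on entry.
* `pwp_fit()`: the Prentice–Williams–Peterson counting-process model =
  Cox stratified on event number with robust patient-clustered variance,
  on the total-time layout. The gap-time variant is not implemented.
  Strata without events are dropped with a warning.
* `nelson_mcf()`: mean cumulative number of events,
  `MCF(t) = Σ_{s≤t} d(s)/n(s)` with `n(s)` the subjects still under
  observation at `s`; cross-checked in tests against the cumulative hazard
  of a `survfit` multi-row fit.
* `incidence_rate()`: events per 100 person-years with *exact Poisson*
  (chi-square) intervals; the ratio uses the log-normal approximation with
  `SE = sqrt(1/a + 1/b)`. Exact intervals were chosen because subgroup
  event counts in such cohorts are small enough for Wald intervals to
  misbehave.

The cutoff sweep fits, for every candidate cutoff, a univariate landmark
Cox model on the dichotomised count plus per-stratum KM medians, and flags
as "optimal" the cutoff maximising the hazard ratio among cutoffs with at
least 5 patients in the high group (smallest cutoff on ties). The full
table is always returned so users can apply other selection rules; see
"Known limitations" for why rules of this type separate poorly between
cutoffs above a true threshold.

## Statistical comparisons

Wilcoxon rank-sum tests are exact (enumeration) when both groups have at
most 25 observations and no ties, otherwise normal approximation with tie
and continuity corrections; signed-rank change-from-baseline tests drop
zero differences and are exact up to 20 nonzero pairs. All tests are
two-sided at α = 0.05. Multiplicity across visits/genes uses the
Bonferroni–Holm step-down adjustment. The per-visit EM comparison uses a
Welch (unequal-variance) t-test: group variances differ by construction
when one group drifts against a boundary at ±1. The "progressor" label for
per-visit comparisons is patient-level — progressed at some point on
protocol — applied to all of that patient's visits.

## The synthetic cohort generator

`generate_cohort()` emulates the joint structure the analysis assumes, with
defaults representing the study conditions:

* **Cohort layout** — 184 patients, up to 9 visits at 3-month intervals
  (months 0–24), HD arms of 54 (lysis) and 55 (no lysis) samples.
  Administrative censoring at 25 months: the 2-year sampling window plus
  the 1-month scheduling allowance, so the month-24 visit is observable.
  Dropout is exponential at 0.04/month, giving roughly 4–5 samples per
  patient. Visit times are nominal (no jitter): scheduling noise would only
  blur the link between the generated covariate states and the fitted ones
  without changing any tested property.
* **Counts** — a patient-level latent burden with three classes:
  structural zeros (8.07%), a negative-binomial typical class (gamma
  burden, mean 1.937, dispersion 0.9), and a 5% high-burden class
  (burden = 5 + lognormal(log 25, 1.5)) supplying the heavy upper tail
  (occasional counts in the thousands, so the truncation rule is
  exercised). Visit-v counts are Poisson around burden × 0.75^(v−1); the
  mixture is calibrated so that at baseline P(count = 0) ≈ 0.39 and
  P(count < 5) ≈ 0.84, which the tests verify at n = 5000.
* **Subtypes** — HR+HER2− 0.576, HR−HER2+ 0.054, HR+HER2+ 0.076, TNBC
  0.201, unknown 0.092.
* **Gene expression** — HD background Ct per gene (CTC-related genes
  37 ± 1, housekeeping 20 ± 0.5, *PTPRC* 24 ± 1, *GYPA* 30 ± 1.5 cycles;
  the no-lysis arm is offset +0.5 cycles). Tumor signal lowers CTC-gene Ct
  by `2.5 × log1p(count)` cycles, weighted for the 8 EM genes by a latent
  polarity state in [−1, 1]: mesenchymal genes by (1 + s), epithelial by
  (1 − s). The polarity drifts +0.05/visit in progressors and −0.05/visit
  in non-progressors from a baseline s ~ N(0, 0.3). A 30% patient subset
  overexpresses *FGFR1* (Ct lowered by 8 cycles), driving that covariate.
* **Events** — progression is a marked Poisson process with intensity
  0.045 · exp(0.811·[count ≥ 5] + 0.545·TNBC + 0.385·[FGFR1 high]) per
  month, covariate states held piecewise-constant between visits exactly as
  the fitted models assume. An event is *fatal* with a covariate-dependent
  mark probability chosen so the fatal sub-process has intensity
  0.010 · exp(1.588·[count ≥ 5] + 1.221·TNBC): death always coincides with
  a progression event, the "progression on the date of death" convention
  holds by construction, and both the recurrent-progression fits and the
  time-dependent death fit are *correctly specified* — each log hazard
  ratio is recoverable by the corresponding pipeline fit. The
  configuration validates that the fatal intensity never exceeds the
  progression intensity. Baseline rates were chosen so the KM median time
  to first progression is about 10–12 months and median overall survival
  lies beyond the 2-year window, as in metastatic breast cancer cohorts of
  this kind. Covariate trajectories are generated first, events second,
  and the EM drift is assigned from the realised progressor status, so EM
  polarity (which does not enter the hazard) avoids any circularity.
* **Clusters** — Poisson with mean 0.28 × (count − 4) when the count
  exceeds 4, zero otherwise; each cluster has at least 2 cells. The
  constant yields about 4% cluster-positive samples.

### What the generator does and does not emulate

It reproduces: the marginal baseline count distribution; declining counts
under therapy; HD-anchored expression with burden-driven signal; an EM
polarity that drifts mesenchymal in progressors; proportional-hazards
effects of the current CTC state, subtype and FGFR1 group on progression
and death; recurrent progressions; dropout. It does **not** emulate: PCR
chemistry or plate/batch effects beyond a single arm offset; measurement
error in counts; informative dropout; cured fractions; the near-30% of
real baseline samples with *no* detectable CTC gene (the synthetic HD
background keeps most genes detectable at low level, so undefined EM
scores are rarer than in real cohorts); or deaths without any prior
progression event. Passing tests therefore demonstrate the *machinery* is
correct under the stated model, not that the model captures every feature
of real CTC data.

## Numerical choices and problem sizes

Cox fits converge to gradient tolerance 1e-9 (≤100 iterations); grid-search
oracles use a 1e-3 coarse grid refined to 1e-6. Ties in ranks fall back to
corrected normal approximations. Confidence level is 95% throughout.
Months = days/30.4375 where dates are converted. The validation suites run
at deliberately moderate sizes — parameter recovery averages 25 replicates
of n = 400 patients; null calibration uses 200 replicates (n = 100 subjects
for simple Cox, n = 200 for the recurrent model, 20 + 20 for rank tests);
the HD tail property uses 500 samples per arm — sizes at which Monte-Carlo
error is comfortably inside the asserted tolerances while the whole suite
runs in minutes on one CPU.

At n = 400 the recurrent-event fit retains a small finite-sample inflation
of the CTC coefficient (of order +10%, within the ±25% recovery band):
event-number strata thin out quickly and robust-variance Cox estimates are
slightly biased away from zero at modest event counts per stratum. This is
a property of the estimator, not an error in the generator, and shrinks
with n.

## Known limitations

* The "optimal cutoff" selection rule (max HR with ≥5 high-group patients)
  cannot sharply distinguish a true threshold from larger cutoffs: any
  cutoff above the threshold yields a high group that still carries the
  full effect, so the expected HR is nearly flat above the truth and
  selection there is noise-driven. Changepoint-style estimators (profile
  partial likelihood over cutoffs, optionally combining the progression
  and death likelihoods) do better but still need more than a couple of
  hundred patients to pin the cutoff reliably; the sweep therefore reports
  the full table rather than promising a consistent estimate.
* The PWP model shares one coefficient vector across strata; effect
  modification by event number is not modelled.
* Interval censoring, frailty terms, accelerated-failure-time and
  multi-state models are out of scope.
* The mixed-effects modelling of clinical benefit is out of scope; only
  the Holm correction used alongside it is provided.
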