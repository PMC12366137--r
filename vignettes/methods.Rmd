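---
title: "Triangulating pre-clinical Alzheimer's liability and blood pressure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating pre-clinical Alzheimer's liability and blood pressure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbpiv)
```

## The estimation problem

Pre-clinical Alzheimer's disease — amyloid and tau pathology present while
cognition is still normal — precedes clinical diagnosis by up to two
decades and cannot be measured in population cohorts. To ask whether this
latent state alters blood pressure (BP), the package implements a
one-sample instrumental-variable design with two deliberately different
instruments:

* **PDIS**, the parental dementia instrument score. Each parent diagnosed
  with all-cause dementia contributes one full unit; each undiagnosed
  parent contributes $(100-\text{age})/100$, their attained age standing
  in for confidence that they will never develop dementia (age 100 being
  roughly the 95th percentile of life expectancy). Because diagnosis is
  rare below age 68, undiagnosed parents aged 68 or younger all contribute
  the capped weight $0.32$. The score is the sum over both parents, in
  $[0, 2]$.
* **PGIS**, a weighted allele score: the participant's effect-allele
  dosages at Alzheimer's-associated variants, weighted by the log odds
  ratios of an external GWAS and summed.

Both instruments are standardized over the analysis sample, and linear
(SBP, DBP, mmHg) or logistic (composite hypertension) regressions report
effects per 1 SD of instrument, from a crude model up a ladder to the
fully adjusted model. The two instruments fail differently — the
family-history proxy through residual confounding and survivor bias, the
allele score through horizontal pleiotropy and population stratification —
so concordance across them (triangulation) carries more causal weight than
either estimate alone. The package reports instrument–outcome
associations, not Wald-scaled causal magnitudes: with an unmeasurable
exposure there is no first stage to scale by.

## Outcome derivation

Mean SBP and DBP come from two readings per visit: the baseline pair is
averaged; a single baseline reading stands alone; if both baseline
readings are missing, the first later visit with any reading is used under
the same rule, each pressure type resolved independently. Automated
readings are preferred over manual ones within a visit. Readings outside
(40, 300) mmHg are treated as device errors and set missing. Participants
on BP-lowering medication have +15 mmHg (SBP) and +10 mmHg (DBP) added —
conservative estimates of average treatment lowering — and the corrected
flag makes the shift impossible to apply twice.

The composite hypertension indicator is the disjunction of self-reported
essential hypertension, antihypertensive use, measured SBP above
140 mmHg, or measured DBP above 90 mmHg. Two choices here were genuinely
open:

* *Strict thresholds.* "Above 140/90" is read strictly; boundary values
  are normotensive.
* *Measured, not corrected, BP in the composite.* Medication already
  enters the composite as its own criterion; correcting BP as well would
  count treatment twice. (Anyone whose corrected BP would cross a
  threshold because of the +15/+10 is already hypertensive via the
  medication criterion, so the choice affects no classification.)

## Eligibility and samples

Withdrawn participants, prevalent dementia, and dementia diagnosed within
the first 5 follow-up years (strict `<` on a continuous years-to-diagnosis
field) are excluded to avoid reverse causality. Allele-score analyses
additionally require passing genotyping QC, self-declared European
ethnicity (guarding population stratification; genetic ancestry inference
is out of scope) and a valid score. Every model ladder is fitted on one
fixed sample — the complete-case sample for the *full* ladder — so
rung-to-rung movement reflects adjustment, never sample shift, and the
instrument SD used for scaling is computed on that same reporting sample
after exclusions. Participants with any missing or unknown parental field
have an invalid PDIS and are excluded from PDIS analyses rather than
imputed; missing genotype dosages likewise invalidate the PGIS by default
(an expected-dosage `2·eaf` imputation mode exists but is off).

## Model ladders

The PDIS ladder is M1 crude/uncorrected, M2 crude/medication-corrected,
M3 +sex, M4 +age, M5 fully adjusted (education, ethnic group, smoking,
BMI, physical activity, salt intake, alcohol, deprivation) with
correction — the pre-specified final model. The PGIS ladder is M1 crude,
M2 +principal components, M3 +sex, M4 +age, all corrected, since the GWAS
weights were already age- and sex-adjusted and confounding of a genetic
score beyond population structure is implausible. Published figures label
rungs only from "crude" to "fully adjusted"; the intermediate ordering
(correction, then sex, then age, then the full roster) was chosen so the
narrated crude-versus-age-adjusted contrast is exactly two named rungs
apart, and the ladder is fully configurable via `model_spec()`. Wald
intervals use the conventional 1.96 throughout (intended use is large
*n*), reference categories are the first factor level (female,
never-smoker, lowest education band), p-values are unadjusted, and a
rank-deficient design is an error naming the collinear columns rather
than a silently dropped coefficient.

## The synthetic cohort: what it emulates

`simulate_cohort()` generates the structure the analysis assumes: a
40–69-year-old cohort, two parents each (parental age = participant age +
N(28, 4)), Hardy–Weinberg parental genotypes with Mendelian transmission,
parental dementia from an age curve (log-odds baseline −3.4 at or below
68, +0.07/year above) plus the parent's own allele score, a shared
familial environment, and optional confounder effects; offspring
pre-clinical AD from a liability threshold (allele-score share
`liability_h2` = 0.45, familial-environment SD 0.7, prevalence 10%); two
readings per visit with 4 mmHg reading noise around a person-level BP
with an 8 mmHg heritable component; medication assigned above 140 mmHg
with probability 0.6 and *lowering measured BP by exactly the 15/10 the
analysis-side correction restores*; and missingness injected completely
at random (0.5% per field, 1.5% for education, 2% per parental field)
so complete-case logic always has work to do.

A liability-threshold model was chosen for the latent exposure because
the design never defines it operationally; the threshold is set from a
configurable prevalence. The "pre-clinical AD raises SBP by `beta_sbp`"
arrow is implemented literally as a mean shift, which is the estimand the
recovery tests check.

### Scenario magnitudes

No quantitative prior exists for the size of the bias effects, so
scenario magnitudes were chosen once — by design analysis and a pilot
simulation at large *n* — to make each qualitative pattern clearly
detectable at the replicate sizes the validation suite uses, and were not
revisited:

* **clean** — no confounding, pleiotropy, survival hazard, or age/sex
  trend in BP; with the default coupling both instruments' fully adjusted
  SBP estimates at *n* = 100,000 sit near +0.13–0.16 mmHg/SD with z ≈ 4–6,
  so a planted 1.5 mmHg effect is recovered with high power while DBP
  (true effect 0) stays null.
* **survivor** — parental death log-hazard 0.002 per mmHg of parental BP
  plus a realistic mid-life BP–age slope (0.7 mmHg/year SBP). The age
  weighting makes the PDIS fall with participant age, so the crude
  estimate is driven negative while age adjustment restores the positive
  causal signal; the allele score, being age-independent, is unmoved. A
  stronger hazard was deliberately avoided: early parental death *raises*
  the age weight of undiagnosed parents, an opposing positive path that
  at large hazards cancels the crude-negative artifact.
* **confounded** — deprivation and adiposity raise parental dementia
  odds (0.25 and 0.20 log-odds/SD) and offspring BP (1.5 and 1.0 mmHg/SD),
  a path full adjustment closes.
* **pleiotropic** — one mid-frequency variant gains a direct 1.5
  mmHg/allele effect on SBP, sized so leave-one-out flags it (its removal
  shifts the estimate by ≈3 reference SEs) without distorting the rest of
  the panel.

### What the simulator does not emulate

Linkage disequilibrium between panel variants, assortative mating,
time-varying BP trajectories, ICD-coded record linkage, genuine ancestry
structure behind the principal components (simulated as noise), and
informative missingness (except where tests plant it). Passing recovery
tests therefore shows the estimators are consistent under the assumed
causal structure — not that real family-history data satisfy it.

## Sensitivity suite

Leave-one-variant-out recomputes the allele score without each variant,
re-standardises it (keeping the per-SD interpretation uniform; the
alternative of freezing the full-panel SD was rejected as mixing scales),
and refits the main model on the same fixed sample; the shift from the
full-panel estimate is reported in units of the reference SE with an
influence flag at |Δ| > 2 — a repository convention, since no published
numeric criterion for "influential" exists. Extended adjustment adds six
metabolic/inflammatory covariates on the complete-case sample for base
plus extras, so the pair is directly comparable; the complete-case
comparison refits the main model on a stricter sample to surface
selection bias from informative missingness.

## Numerical choices and problem sizes

Linear models are solved by pivoted QR (`.lm.fit`) with conventional
SEs; the suite verifies agreement with a normal-equations oracle to
1e−10. Logistic models use IRLS with Wald SEs; non-convergence and
(quasi-)complete separation — detected by extreme fitted probabilities
together with an exploding coefficient or SE — are explicit errors, never
silent estimates, and the suite checks the 2×2 closed form to 1e−8.
Degenerate instruments (zero SD) and one-class outcomes are errors.
Palindromic variants are dropped in harmonisation when either frequency
lies within 0.08 of 0.5, standard practice where the source only promises
a frequency "check".

The validation suite uses 200 replicates at *n* = 100,000 for parameter
recovery, 100 at *n* = 30,000 for the survivor sign-flip and 100 paired
runs at *n* = 25,000 for leave-one-out — sizes at which each designed
effect has z ≳ 2.5 per replicate, so replicate-level pass rates are
governed by the design rather than by luck. Allele-score stability under
age/sex adjustment is judged on the mean estimate change across
replicates against half the mean SE: the within-replicate change between
nested models is dominated by the variance the added covariates explain,
so a per-replicate bound would measure noise, not bias.

## Known limitations

Estimates are instrument–outcome associations per SD of score, not
mmHg-per-unit-exposure causal effects. The relevance check (association
with the participant's own diagnosed dementia) substitutes for an
unobtainable first-stage F statistic. Two-sample MR estimators
(MR-Egger, weighted median) are intentionally absent — they target a
different design. Real-data concerns such as drug-name mapping for
BP-lowering medication, ICD code lists, and genetic ancestry inference
are out of scope; the synthetic flags stand in for them.
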