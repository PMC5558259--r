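---
title: "Methods: score construction, risk updating and trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score construction, risk updating and trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grstrial)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical conventions adopted where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The genetic risk score

The score is a linear weighted sum of effect-allele dosages over 19 CAD
risk loci, the weights being per-allele log odds ratios from genome-wide
association results. Normalization is against a reference cohort: the
z-score uses the reference sample mean and SD (n−1 denominator), and the
percentile is the fraction of reference scores *strictly below* the
participant's raw score. The strictly-below convention was chosen because
it is deterministic, testable at boundaries (a score below every reference
value has percentile exactly 0), and consistent with reading "above the
population median" as percentile > 0.5. When no empirical reference is
carried (e.g. a summary-only reference JSON), the percentile falls back to
the normal approximation `pnorm(z)`; with 19 loci the central limit
approximation of the score distribution is adequate for the 0.5 cut used
by the subgroup split.

Two deliberate data-hygiene choices:

* **The bundled weight table is a placeholder.** The 19 rsids and the six
  proxy relations are real; the numeric weights and alleles are synthetic
  (flagged in the file itself), because the source study prints the locus
  list but not the effect sizes. Every numeric test in the package uses
  synthetic weights; nothing downstream depends on the placeholder values.
* **Missing dosages are never silently imputed.** The default policy is an
  error; opting into mean imputation replaces a gap with `2p` (the
  Hardy–Weinberg expectation under effect-allele frequency `p`, supplied
  explicitly) and surfaces the count in `n_missing_imputed`. Under
  imputation the raw score uses the fractional fill while `allele_count`
  keeps summing observed dosages only, preserving its integer meaning as a
  count of observed high-risk alleles.

Dosages always count effect alleles. The VCF reader owns orientation:
ALT-vs-effect matches are used directly, swapped REF/ALT records are
flipped (`2 − count`), records matching neither orientation become missing
with a warning, and strand-ambiguous (A/T, C/G) loci are reported and can
be dropped by flag. The scoring module therefore never sees allele
ambiguity.

## 2. Framingham risks and the genetic update

The risk engine is coefficient-table-driven: a JSON table supplies per-sex
term lists (covariate, `log` or `identity` transform, beta, optional
treated/untreated blood-pressure condition), a baseline survival `S₀` over
the horizon, and the derivation cohort's mean linear predictor; risk is
the Cox form `1 − S₀^exp(LP − mean LP)`, clamped to `[0, 1]`. Tables are
user-overridable, so no calculator variant is hard-coded.

The bundled 10-year table is the published sex-specific general-CVD
equation; the test suite freezes its published female worked example
(61-year-old smoker, total cholesterol 180, HDL 47, untreated SBP 124,
non-diabetic → 10.48%), which reproduces to four decimals. The male row is
covered by structural tests (an all-mean profile returns `1 − S₀`,
monotonicity in each covariate, sex dispatch), because the male worked
example could not be independently verified offline. The bundled 30-year
table is a **clearly flagged synthetic extrapolation**: the same covariate
betas with `S₀(30) = S₀(10)³`, i.e. a constant-hazard assumption. It
ignores competing mortality and therefore overstates true 30-year event
risk at older ages; it is used only for the trial's 30-year eligibility
branch, whose threshold behaviour is tested on constructed risks rather
than on this table. Out-of-range covariates warn and are still evaluated,
matching how such calculators are used in screening practice.

"Relative risk regression" is operationalized as a log-link binomial GLM
of the event indicator on the GRS z-score, age (linear) and sex (one
indicator) — the standard meaning of the term, so that the exponentiated
z coefficient is a relative risk per SD. Log-binomial fits can fail off
the boundary; the engine then falls back to the modified-Poisson
estimator, which targets the same parameter. Confidence intervals always
use robust HC0 sandwich standard errors (computed in-package from the GLM
score contributions), which keeps the Poisson fallback valid and the
binomial path robust to minor link misspecification. The genetic update is
multiplicative, `min(base₁₀ · exp(β z), cap)` with cap 1 by default, since
an unbounded multiplicative update can exceed a probability's range.

## 3. Trial mechanics

Eligibility follows the enrollment wording literally: the 10-year
threshold is **inclusive** ("at least 6%") and the 30-year threshold
**strict** (">20%"); the allowed-ethnicity set is configuration (default:
the three stated groups), because the trial's own baseline table contains
participants outside them and both behaviours must be representable.
Failed criteria are enumerated as reasons, not collapsed into a boolean.

Randomization is permuted blocks: each block of 8 is an independent
uniform permutation of four copies of each arm, a trailing short block
uses the leading entries of one more permuted block, and the whole
sequence is a pure function of the seed. Consequences tested as
invariants: complete blocks are always 4/4, accrual imbalance never
exceeds 4, and the marginal assignment probability at every position is
1/2. Each randomized subsystem (randomization, allele-frequency draw,
cohort and trial simulation) derives its own named RNG stream from the
master seed and restores the caller's RNG state afterwards, so components
are independently reproducible and composable.

## 4. Missing data and the Hodges–Lehmann analysis

The carry-forward rules reproduce the study's stated procedure, with
provenance recorded per value (`observed` / `carried_forward`), and are
never allowed to fabricate a value absent from all visits:

* **Lipids and clinic measurements**: a missing 3-month value is imputed
  from baseline; participants without a post-final measurement are
  excluded. The no-imputation mode (the report's second LDL row) disables
  the baseline fill, so its analyzed n is always ≤ the imputed row's —
  the split pattern the trial's outcome table shows.
* **Questionnaires**: items are carried forward from the most recent prior
  visit; a participant whose questionnaire is entirely missing at the
  final visit *and* at baseline or the 3-month visit is excluded for that
  questionnaire. Carrying a 3-month response into a missing final visit
  contributes an exact zero change — a conservative, power-preserving
  convention inherited from the study design, and one reason questionnaire
  change distributions are tie-rich.

The between-arm comparison of 3-to-6-month changes uses the two-sample
Hodges–Lehmann estimator (median of all `m·n` pairwise differences,
midpoint of the central pair when `m·n` is even) with the
Wilcoxon–Mann–Whitney test and its inversion CI — the standard pairing
behind a "difference in medians with CI" presentation. Numerical
conventions, fixed a priori:

* exact null distribution for the p-value and CI whenever `m·n ≤ 10,000`
  and there are no ties;
* otherwise midranks with tie-corrected variance, **without** continuity
  correction. At this trial's arm sizes the corrected approximation is
  noticeably conservative for the heavily tied questionnaire outcomes;
  omitting the correction keeps the nominal level, which the acceptance
  suite verifies empirically (per-outcome type-I error within
  [0.03, 0.07] over 500 null trials);
* with extreme tie mass the inverted CI can collapse to a point (e.g.
  `[0, 0]` when most pairwise differences are zero); this is a property of
  the inversion, reported as-is.

Medication use is compared by two-sided Fisher exact tests (the study
reports proportions with p-values but names no test; the choice is logged
as an assumption). Fisher's test is intrinsically conservative at n ≈ 30
per arm, so the medication rows are excluded from the type-I calibration
band, which applies to the ten shift rows. No multiplicity adjustment is
applied (none was in the study); the report carries its comparison count.

The default report has 14 rows — ten shift outcomes (LDL twice, HDL,
systolic and diastolic BP, weight, diet, activity, anxiety, stages of
change) plus four medication comparisons — mirroring the study's outcome
table row-for-row.

Subgroups: the high-GRS analysis keeps the **full** standard-of-care arm
as comparator (inferred from the unchanged control sample sizes in the
study's subgroup table; config-overridable), restricting only the GRS arm
to percentile > 0.5. The attitude subgroup splits both arms strictly above
the within-study median of the baseline beliefs-about-medicines aggregate
and flags an all-tied aggregate as degenerate rather than splitting
arbitrarily.

## 5. What the synthetic generator emulates — and what it does not

The generator encodes the stated world of the analysis:

* **Reference cohort** (default n = 8,734): independent Hardy–Weinberg
  genotypes at the 19 loci; allele frequencies drawn once, uniformly in
  [0.1, 0.9] from the seed (none are published; the draw keeps scores
  non-degenerate without inventing published values); event probability
  log-linear in the self-normalized z with default truth RR = 1.18 per SD,
  baseline event rate 0.08 at z = 0 (a typical 10-year incident-CHD rate
  for a middle-aged cohort), log-additive age (0.04/year) and sex (log 2)
  terms. Configurations that could push a probability above 1 are rejected
  before sampling. The log-linear form makes the recovery target
  well-posed: the regression estimates exactly the encoded parameter.
* **Trial** (default n = 94): covariates drawn on the scale of the study's
  baseline table and rejection-sampled to satisfy eligibility by
  construction; blocks of 8; monotone dropout with marginal attendance
  0.82 / 0.69 (the reported retention); outcome trajectories
  `v2 = baseline + drift + ε`, `v3 = v2 + drift + arm effect + ε`, with
  the between-visit noise SD set per outcome to the study's printed change
  SDs (LDL 28 mg/dl, weight 3.5 kg, ...), so injected effects translate
  one-to-one into the analyzed change and power behaviour is realistic.
  Item missingness defaults (lipids 8%, clinic measurements 0%,
  questionnaires 35%) were set from the study's printed per-outcome
  analysis counts relative to its completer counts, before any acceptance
  criterion was evaluated.

Deliberately not emulated: linkage disequilibrium between loci, population
stratification, informative missingness beyond a single arm-differential
dropout knob, seasonal/visit-window effects, and the study's actual score
distribution (mean allele count 18.1, SD 2.5), which cannot be reproduced
without the unpublished weights and frequencies. A green test therefore
establishes that the *pipeline* is correct under the assumed structure —
unbiased parameter recovery, calibrated tests, faithful rule application —
not that it reproduces the trial's participant-level results, which were
never released.

## 6. Open choices resolved

* **Weighted vs unweighted normalization**: whether the reference
  "distribution of scores" used the weighted score or the raw allele count
  is ambiguous in the source; both are computed, the weighted score is the
  normalization default (a weight table of ones recovers the unweighted
  behaviour, and a test pins that equivalence).
* **Which Framingham calculator**: not named in the source; resolved by
  making the engine table-driven and bundling the one published table with
  a reproducible worked example (general CVD, 10-year) rather than
  guessing an unverifiable hard-CHD table. The eligibility thresholds act
  on whatever tables the configuration selects.
* **Binary-outcome vs survival formulation of the reference regression**:
  implemented as the binary log-link form, matching the generator's event
  model and the "relative risk regression" phrasing; a time-to-event
  formulation is out of scope.
* **Mid-block termination**: enrollment may stop mid-block; the trailing
  incomplete block simply truncates a full permuted block, preserving the
  imbalance bound.

## 7. Known limitations

The 30-year table is an extrapolation, suitable only for exercising the
eligibility branch. The log-binomial fit can be fragile near high fitted
probabilities (mitigated by the Poisson fallback and flagged in the fit's
`model_family`). The exact rank-sum path refuses nothing at `m·n ≤ 10⁴`
but silently switches to the approximation with ties, as conventional.
Percentiles from a summary-only reference rely on normality of the score.
The CLI is a thin veneer over the R API; it does not attempt schema
migration of configs across package versions.
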