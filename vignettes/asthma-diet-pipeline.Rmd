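---
title: "Asthma phenotyping, diet scoring, and odds-ratio screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asthma phenotyping, diet scoring, and odds-ratio screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiasthma)
```

## The analysis model

`epiasthma` implements the standard analysis skeleton of a cross-sectional
ISAAC-questionnaire allergy survey, anchored to a cohort of 10,736 young
Chinese adults recruited in Singapore. It has three scientific layers and
two infrastructure layers.

### Phenotype taxonomy

Subjects are classified hierarchically:

* **Ever asthma** — affirmative answer to the lifetime-asthma question.
* **Atopy** — a skin-prick-test (SPT) wheal of at least 3 mm to any tested
  allergen (*Blomia tropicalis*, *Dermatophagoides pteronyssinus*). The
  3 mm threshold (`wheal_threshold_mm`) is the standard SPT positivity
  criterion and is exposed as a parameter.
* **Atopic asthma** — ever asthma and atopy.
* **Current asthma** — ever asthma plus at least one of three symptoms in
  the past 12 months: wheeze, dry night cough without a cold or flu, or an
  asthma exacerbation. A subject who never had asthma is not a current case
  regardless of symptoms; an ever case with all three symptom answers
  missing has missing current status; an ever case with any affirmative
  symptom is current even if the other answers are missing (Kleene
  three-valued logic throughout).
* **Variants among current cases** — wheeze-variant asthma (WVA: any
  12-month wheeze), exercise-induced asthma (EIA: exercise-provoked wheeze,
  *constrained to WVA cases*), and cough-variant asthma (CVA: dry night
  cough). They are non-mutually exclusive and undefined outside current
  cases.

The EIA definition deserves a note. Narrative definitions of EIA sometimes
read as "wheezy chest in the last 12 months", which would make EIA
indistinguishable from WVA; reported variant counts, however, treat EIA as
a strict subset of WVA (e.g. 192 EIA of 408 WVA cases, 47.1%). We therefore
define WVA as any 12-month wheeze and EIA as exercise-provoked wheeze among
WVA cases. This is the only reading under which the published variant
arithmetic is internally consistent, and it determines the eight-cell
overlap uniquely from the printed marginals: among the 588 current cases
with complete variant data, (WVA, EIA, CVA) cells TTT = 106, TTF = 86,
TFT = 71, TFF = 145, FFT = 180, FFF = 0.

Variant summaries always report the complete-data sub-denominator (588 of
679 current cases) next to the current-case count; the two are never
silently interchanged.

### The diet score

The Quality of Diet based on Glycemic Index Score (QDGIS) dichotomizes
foods at a glycemic index of 55. Four food groups are high-GI
(burgers/fast food, cereals, rice, potatoes) and six are low-GI (fruits,
vegetables, pulses, nuts, milk, probiotic drinks); the remaining six
questionnaire foods (meat, seafood, pasta, butter, margarine, eggs) carry
no GI class and are not scored — scoring them is an error, not a silent
zero. Frequency weights are 7 (most or all days), 2 (once or twice per
week), 0 (never or only occasionally), signed negative for high-GI and
positive for low-GI foods, so the attainable range is [−28, +42].

The published category boundaries contain an internal inconsistency: "poor"
is stated as score > 2, which overlaps the "moderate" interval [2, 10) and
leaves scores below 2 unmapped. We resolve *poor ⇔ score < 2*: it is the
unique reading that makes the three printed intervals a partition of the
range and is consistent with higher scores indicating a lower-GI (better)
diet. The boundary cases are therefore: 1 → poor, 2 → moderate, 10 → good.

Missing food items default to **propagate** (any missing scored item gives
a missing score), matching the observation that the published GI-level
missing counts exceed any single food's missing count — consistent with
complete-case scoring. A `zero-impute` policy is provided as an explicit
alternative since the original handling is unstated; the result records
`n_missing_items` either way.

### Association analysis

For each exposure the analysis is per-exposure complete-case: subjects
missing that exposure or the outcome are excluded and counted, which is why
each exposure has its own analyzed N. Unadjusted odds ratios come from the
2×2 sub-table of one level against the reference level,
OR = ad/bc, with the Wald interval
exp(ln OR ± z₀.₉₇₅·√(1/a+1/b+1/c+1/d)) using the exact quantile
Φ⁻¹(0.975) = 1.959964, and a two-sided normal p-value on ln OR / SE.
Zero cells raise an error; an optional Haldane–Anscombe +0.5 correction on
all four cells can be enabled (off by default — the reference tables
contain no zero cells).

Adjusted odds ratios exponentiate coefficients of `logit_fit()`, a
self-contained binomial logistic regression solved by iteratively
reweighted least squares: starting at β = 0, each iteration solves the
weighted least-squares problem with weights μ(1−μ) and working response
η + (y−μ)/μ(1−μ); convergence is the largest absolute coefficient change
falling below `tol` (default 1e−8, default cap 25 iterations). The
covariance is the inverse Fisher information at the optimum. Numerical
guards: weights floored at 1e−12; quasi-complete separation (fitted
probabilities within 1e−10 of 0/1 together with a coefficient beyond ±10)
is reported as an error naming the worst term; rank-deficient designs and
non-convergence are errors, the latter carrying the iteration trace; fits
with fewer than ten complete cases per design column warn. The test suite
cross-checks coefficients, covariance, deviance, and predictions against
`stats::glm` — the independent oracle, never the implementation.

`association_screen()` mirrors the per-exposure modelling convention of the
source tables: each exposure's adjusted model contains that exposure plus
the adjustment set only. The default adjustment set is
{gender, parental history of asthma}; the narrative alternative ("age and
gender") appears once in the source's diet section but the archival table
footnotes of both outcome tables state gender and parental asthma, so the
footnote set is the default and any list can be passed. Significance is
flagged at α (default 0.05) on the adjusted p-value when an adjustment set
is present, otherwise on the unadjusted one — no multiple-testing
correction gates the flag, matching the source's raw p < 0.05 rule; a
Benjamini–Hochberg column is emitted as supplementary output only.

Two comparison-group conventions exist for current asthma: against all
non-current subjects, or within ever-asthma cases. The published current
table denominators (1,370 + 679 = 2,049) show the comparison is within
ever cases, so that is the pipeline default (`current_within_ever = TRUE`),
with the other convention available.

Reference levels are the first printed category of each variable
("never or only occasionally" for foods and activity, "< SGD2000" for
income, "less than 1 h" for screen time, "poor" for GI level). The gender
reference is configurable (`set_reference()`) because lifetime- and
current-asthma gender effects are conventionally reported in opposite
directions (male-vs-female and female-vs-male respectively).

## The synthetic-data generator

`simulate_cohort()` draws, in order: covariates independently from
categorical marginals; lifetime asthma from a logistic model
η = β₀ + Σ βₗ·1[covariate = l]; a latent current state among ever cases; the
three defining symptoms conditioned on that state (current cases are
redrawn until at least one symptom is affirmative, so the latent state and
the classification rule agree); exercise wheeze conditioned on wheeze; SPT
wheals from truncated normal distributions by latent atopy status (atopic
subjects are guaranteed at least one wheal ≥ 3 mm; controls are drawn
valid); and finally MCAR missingness per variable. Identical spec and seed
give identical cohorts, and the latent truth is returned separately for
recovery testing — analysis code never reads it.

Defaults are the study conditions where published: n = 10,736; female
57.6%; income 22.7/34.0/19.5/23.8%; housing 67.5/19.0/13.5%; born in
Singapore 69.1%; drug allergy 11.7%; age ~ N(22.5, 5.2²) truncated at 18;
dietary marginals equal to the row totals of the packaged diet tables;
outcome intercept −1.65 giving roughly the 19.1% ever prevalence, with
male log-OR log(1.387); current-given-ever 0.331; symptom rates 0.694
(wheeze), 0.607 (cough), 0.471 (exercise-given-wheeze); atopy 0.752 among
ever cases. Where the source prints nothing (lifestyle and family-history
marginals, the exacerbation rate 0.30, atopy 0.55 among non-ever subjects,
the parental-asthma effect 1.35 on the log-odds scale — the crude log 4.78
attenuated as a plausible conditional effect, wheal means 6 mm/1 mm), we
chose once what is realistic for a young-adult university cohort in a
tropical, house-dust-mite-dominated setting, and the missingness rates
echo the published per-variable NA counts (0.2% gender … 5.5% housing, 5%
symptoms and SPT).

What the generator does **not** emulate: covariate dependence (covariates
are independent by default, whereas real income, housing, and diet
correlate), MAR/MNAR missingness (only MCAR), age effects on the outcome
unless requested, and any clustering or recruitment structure. Passing
recovery and coverage tests on these cohorts therefore validates the
estimation machinery — not the epidemiological conclusions of any real
cohort, and not robustness to informative missingness.

`expand_printed_table()` is the bridge to published evidence: it turns a
levels × outcome counts table into one minimal record per count unit, so
`build_contingency()` on the expansion returns the inputs verbatim and the
unadjusted odds-ratio path can be checked against printed values to three
decimals. Published **adjusted** odds ratios are out of reach at desk
scale — they depend on the study's joint covariate distribution, which
marginal counts do not determine — so the adjusted path is validated by
parameter recovery instead.

## Numerical and validation choices

* Percentages are rounded half-up to one decimal (2049/10736 → 19.1);
  base `round()` is round-half-even and is not used for reporting.
* Level matching is case-insensitive after whitespace normalization;
  missingness is a first-class `NA`, never a sentinel value, with one
  configurable missing token at the file boundary (default: empty string).
* Validation problem sizes, chosen to give tight Monte-Carlo error at
  interactive runtimes: oracle agreement on 100 random tables with cells in
  [5, 5000] (tolerance 1e−6 relative); recovery and 95% CI coverage over
  100 replicates of n = 10,000 (bias bound 0.05 on the log scale, coverage
  band [92%, 98%]); type-I error of the significance flag over 200 null
  cohorts of n = 4,000 with 16 exposures (band [3.5%, 6.5%]); diet-score
  properties by exhaustive enumeration of all 3¹⁰ = 59,049 diets. The null
  cohorts use n = 4,000 so that the rarest food-frequency cells stay
  comfortably away from zero counts under the null prevalence.
* Marginal fidelity of the generator is checked at n = 10⁵ within three
  binomial standard deviations.

## Known limitations

* The IRLS solver targets the dense, low-dimensional designs of
  questionnaire epidemiology; it has no penalization (no Firth correction),
  so separated designs are an error rather than a shrunken estimate.
* Wald intervals and p-values are first-order asymptotic; for the very
  sparse cells where they degrade, the package reports the cells so the
  user can see the sparsity.
* `strict_spt_qc` invalidates SPT records with failed controls but is off
  by default, since the source describes no control-based exclusions.
* The reconstruction of the published participant flow
  (`reconstruct_phenotypes()`) realizes the printed marginal counts
  exactly but is synthetic at the subject level; it supports arithmetic
  checks, not subject-level inference.
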