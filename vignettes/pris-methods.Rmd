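---
title: "PRIS: score definition, validation workflow, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PRIS: score definition, validation workflow, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pris)
```

## The problem

Sublingual allergen immunotherapy (SLIT) commits a patient to years of
treatment with uncertain individual benefit. The Predictive Response to
Immunotherapy Score (PRIS) condenses eight routinely collected clinical
and laboratory parameters into a single 20–100 point score intended to
rank patients by their expected symptom improvement before treatment
begins. This package implements the score, the eligibility and
dominant-allergen rules that feed it, the outcome indices used to
validate it, the statistical battery of that validation, and a seeded
simulator so the whole chain can be exercised and tested without
patient data.

## Score model and assumptions

PRIS is a plain additive point score: each parameter is binned into 3–5
ordered categories and the category points are summed (see the score
table in the README and `?pris_components`). Because the parameters'
minima are 3/3/3/4/3/4/0/0 and maxima 15/9/9/16/12/12/12/15, the total
is bounded in [20, 100]; `pris_score_grid()` enumerates all
5·3·3·4·4·3·3·4 = 25,920 category combinations and the test suite
verifies the bounds exhaustively, as well as monotonicity (raising any
single parameter's category never lowers the total). The score makes no
interaction or weighting assumptions — the point values are fixed by
construction and this package deliberately implements them verbatim
(`score_*` functions); re-weighting or learning the points is a
non-goal.

Two inputs need resolution rules for polysensitized patients, and both
are genuinely open design choices:

* **s/t ratio input.** The specific/total IgE ratio of *which* allergen?
  We use the extract-level specific IgE of the highest-IgE dominant
  allergen, because the dominant allergen is the one driving the SLIT
  prescription and the ratio is meant to index how focused the IgE
  response is on it.
* **CRD input.** The component-resolved category is the *maximum*
  category over the molecular components of the dominant source(s)
  (e.g. Phl p1/Phl p5 for grass). If no component of a dominant source
  was assayed, the category is `negative` (0 points) — the score's own
  floor for this parameter, consistent with CRD being an optional
  awareness-raising assay.
* **Clinical tier.** `rhinitis + other_allergies` without asthma is not
  a row of the score table; we score it at the one-comorbidity tier
  (6 points) and flag it (`extrapolated_clinical`) so users can audit
  how often the extrapolation fires.

Boundary conventions: every printed category endpoint is inclusive
(age 12 → 15, age 13 → 12; onset 3 → 9; s/t = 0.2 → 12; component IgE
3.50 → high positive), fractional ages/onsets are floored to whole
years, and the first onset bin is read as ≤ 3 years.

## Eligibility and dominant allergens

`screen_eligibility()` applies the enrolment rules: age ≥ 6 years,
asthma (when present) adequately controlled, no nasal polyposis, no
profilin allergy (component IgE to Bet v2 ≥ 0.35 kUA/L), and at least
one positive skin prick test *and* one positive specific IgE. Asthma
control uses the Asthma Control Test with a controlled threshold of
ACT ≥ 20 — the conventional cutoff separating "well controlled" from
"not well controlled" — configurable because practices differ; a
missing ACT in an asthmatic is an error rather than a silent pass.

`identify_dominant_allergens()` formalizes the prescription rule: sort
positive sensitizations by specific IgE (ties by wheal, then label) and
take the shortest prefix whose members all exceed all non-members by
**both** a ≥ 5 mm wheal difference **and** ≥ 0.5 log₁₀ units of
specific IgE. Both margins are required (the conjunctive reading of the
rule); requiring either margin alone would declare more single-dominant
patients. "Half a logarithm" is taken as log₁₀ — IgE spans orders of
magnitude and is conventionally displayed on a decimal log scale; a
natural-log reading (0.5 ln ≈ 0.217 log₁₀) would make the margin much
weaker. If no proper prefix separates, all positive allergens are
co-dominant and the reported separations are 0. Specific IgE is floored
at 0.01 kUA/L (below assay range) before logs so that margins stay
finite for sources positive only at skin testing. The test suite checks
this prefix algorithm against a brute-force enumeration of all candidate
subsets on panels of up to five allergens, plus permutation- and
scale-invariance properties.

## Outcomes

The mean symptom score `mss()` is the unweighted arithmetic mean of all
VAS items recorded at a timepoint — symptom severity items plus the
frequency, exacerbation and on-demand-medication items, making it a
combined symptom and medication score on [0, 100]. No item weights are
used; asthmatic patients contribute their asthma items, rhinitis-only
patients do not, and the mean remains comparable across the two. The
efficacy index `delta_mss()` is the percentage drop from baseline, so it
is undefined at MSS-0 = 0 (an error) and scale-invariant otherwise.
Group-level ΔMSS(%) is reported as the mean of per-patient percentages,
not the percentage change of group means — per-patient averaging is what
makes the group value the expectation of the individual index. Dropouts
are excluded from follow-up analyses; no imputation is attempted.

## Statistical battery

* `sample_size_pearson()` / `power_pearson()` use the Fisher-z
  approximation; the power function includes both rejection tails so its
  size is exactly α at r = 0. The design point r = 0.3, α = 0.05,
  power 0.80 gives n = 85. `power_pearson_mc()` is an independent
  Monte-Carlo check using the exact t test on simulated bivariate-normal
  samples.
* `simple_regression()` is OLS with R reported as the correlation
  magnitude and F on (1, n − 2) df. Note: the identity
  F = R²/(1 − R²)(n − 2) is exact, and n = 98 gives df₂ = 96 — a
  denominator of 97 at n = 98 is not obtainable from simple OLS, so this
  package reports n − 2.
* `rm_anova()` computes the within-subject one-way F from the
  subject × time sum-of-squares decomposition (validated in tests
  against `aov()` with an `Error()` stratum). Sphericity is uncorrected
  by default — with only three levels the distortion is limited and the
  Greenhouse–Geisser correction is available via `gg = TRUE` (epsilon is
  always reported). Pairwise timepoint contrasts are paired t tests,
  Bonferroni-adjusted by default.
* `oneway_anova_posthoc()` wraps `aov()` with Tukey HSD post-hoc
  comparisons by default (Bonferroni pairwise t tests as the
  alternative) — Tukey is the standard choice when all pairwise
  contrasts of a between-subject factor are of interest.
* `component_regression()` regresses ΔMSS-24 *as a proportion* (0–1) on
  each parameter's category indicators with the lowest-scoring category
  as reference; the proportion scale keeps the coefficients in the
  0.01–0.2 range typical for such category effects.
* No multiplicity control is applied across the battery as a whole; the
  battery mirrors a single pre-specified validation analysis.

## The synthetic cohort generator

`generate_cohort()` exists so that every operation above is testable
end-to-end. Its defaults are fixed reference conditions, not tuning
knobs: 110 enrolled patients; age truncated-normal 24.87 ± 10.80 years
on [6, 63] (the sampling location is shifted so the mean of whole-year
ages matches the target after truncation and flooring); 61.8 % male;
50 % concomitant asthma, of whom 20 % carry a further allergic
comorbidity (a package choice; a modest share keeps the three-tier
clinical parameter populated without dominating); 10.9 % dropout,
independent of score and response; baseline MSS 80.97 ± 8.24; an
allergen mix dominated by pellitory, grass and house dust mite (derived
from SLIT prescription frequencies, with one pseudo-count for never
prescribed extracts); and plausible category distributions for onset,
sensitization count, exposure count, s/t ratio, CRD and dominance
(onset skewed to recent, two thirds of patients with a single dominant
allergen — see `?cohort_config` for the exact vectors).

The response is generated at the patient level:
ΔMSS-24(%) = a + b·PRIS + ε with ε ~ N(0, σ). `calibrate_link()` picks
b = r/√(1 − r²)·σ/σ₍PRIS₎ so the *population* correlation equals a
target (default 0.62, a strong predictive regime), where σ₍PRIS₎ is
estimated once from 20,000 deterministic covariate draws — this
accounts for the dependencies the sampler introduces (exposure and
dominance clamped to the sensitization count, onset clamped to age)
that a closed-form independence calculation would miss. The intercept
sets the mean response (default 67.71 %). σ defaults to 13 percentage
points, which makes the total response SD ≈ 16.6, in the range of the
per-stratum spreads (≈ 8–18) such cohorts show. ΔMSS-12 is
ΔMSS-24 − gap with gap ~ N(6.36, 12.5): the mean is the additional
improvement accrued in the second year and the SD is set so the
12-month MSS spread matches its reference value (≈ 16.9). Note that
a mean 12-vs-24-month difference of ~5 MSS points at n ≈ 98 is
reliably *significant* in a paired test — a cohort in which that
contrast comes out non-significant despite such mean separation is a
borderline single realization, and the simulator will not typically
reproduce it; the acceptance suite documents this.

VAS items are back-solved from the latent MSS (all items set equal to
it), because every analysis consumes only MSS summaries; responses are
clipped to [−25, 100] and MSS to [0, 100] (clip events are counted in
the `n_clipped` attribute). Raw measurements are realized to match the
sampled categories exactly — dominant extracts share one high
wheal/IgE value, non-dominant ones sit 6 mm and 0.7 log₁₀ below, the
total IgE is `specific / ratio` — so re-deriving PRIS from the raw
tables reproduces the sampled total for every patient (a test
invariant).

What the generator does **not** emulate: seasonal symptom dynamics,
product differences, immunological trajectories, correlations between
covariates (age and onset are linked only through feasibility clamps),
measurement noise in SPT/IgE, and item-level VAS heterogeneity. Passing
tests therefore show that the *pipeline* is correct and that the
statistical machinery behaves as advertised under a known
data-generating process — not that the score is valid on real patients.

## Problem sizes and numerical conventions

The test suite uses cohorts of 25–300 patients (one 5,000-patient draw
for distributional checks), 200 seeded replicates for the calibrated
simulation properties, 10,000 replicates for the ANOVA type-I error
calibration, and 20,000 replicates for Monte-Carlo power; these sizes
make the binomial/simulation standard errors small enough for 3-SE
assertions while keeping a full run in a few minutes. Doubles are
serialized with 17 significant digits (`%.17g`) so cohort CSVs
round-trip bit-exactly. Degenerate inputs fail loudly: empty item sets,
zero baselines, constant predictors, missing repeated-measures cells,
single-category parameters (skipped with a warning) and out-of-range
scores all raise informative errors rather than propagating NAs.

## Known limitations

* The score table is implemented verbatim; no calibration, shrinkage or
  validation on external data is provided.
* The eligibility rule requires both a positive SPT and a positive
  specific IgE; cohorts screened under an either/or convention need a
  relaxed screen.
* `rm_anova()` assumes complete cases; unbalanced longitudinal designs
  need mixed models, which are out of scope.
* The simulator's independence assumptions (above) make it a
  correctness harness, not an epidemiological model.
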