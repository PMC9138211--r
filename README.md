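# pris

Allergen immunotherapy (AIT) is the only disease-modifying treatment for
IgE-mediated allergic rhinitis and asthma, but it is long (3+ years),
expensive, and 10–40 % of treated patients see little benefit. `pris`
implements the **Predictive Response to Immunotherapy Score (PRIS)** — an
eight-parameter clinical point score designed to estimate, *before*
sublingual immunotherapy (SLIT) is prescribed, how much symptom
improvement a patient can expect — together with the complete workflow
needed to validate such a score on a longitudinal cohort. It is written
for allergists and biostatisticians who want to apply the score to their
own cohorts or stress-test it on simulated ones.

## The score and the outcome index

Each of eight parameters is mapped to points and summed,
PRIS = Σᵢ sᵢ ∈ [20, 100]:

| parameter | categories → points |
|---|---|
| age (years) | 0–12 → 15, 13–18 → 12, 19–28 → 9, 29–38 → 6, >38 → 3 |
| clinical features | rhinitis → 9, +asthma → 6, +asthma+other allergies → 3 |
| disease onset (years) | ≤3 → 9, 4–10 → 6, >10 → 3 |
| n. allergen sensitizations | 1 → 16, 2–3 → 12, 4–5 → 8, >5 → 4 |
| symptoms on exposure to n allergens | 1 → 12, 2 → 9, 3 → 6, ≥4 → 3 |
| specific/total IgE ratio | ≥0.2 → 12, 0.05–0.2 → 8, <0.05 → 4 |
| CRD for major allergens (kUA/L) | ≥3.50 → 12, 0.35–3.50 → 6, <0.35 → 0 |
| n. dominant allergens | 1 → 15, 2 → 10, 3 → 5, >3 → 0 |

Sensitizations are counted as the union of positive skin prick tests
(wheal ≥ 3 mm) and positive specific IgE (≥ 0.35 kUA/L); the *dominant*
allergens — those prescribed for SLIT — are the ones separated from all
other sensitizations by **both** a wheal margin (≥ 5 mm) and a
specific-IgE margin (≥ 0.5 log₁₀ units).

Treatment response is measured on visual-analogue scales (VAS, 0–100)
collected at baseline (T0) and after 12 and 24 months of SLIT. The mean
symptom score MSS-t is the unweighted mean of all VAS items at
timepoint t, and the efficacy index is

ΔMSS-t(%) = (MSS-0 − MSS-t) / MSS-0 × 100,

stratified into response bands (≥75 very high, 50–75 high, 25–50 mild,
<25 low). The validation battery regresses ΔMSS-24(%) on PRIS, runs a
repeated-measures ANOVA on MSS over time, a one-way ANOVA with Tukey
post-hoc tests across PRIS strata (Q1 ≥ 80, Q2 60–79, Q3 40–59,
Q4 < 40), per-parameter category regressions, and the Fisher-z power
analysis behind the design (n = 85 for 80 % power to detect r = 0.3 at
two-tailed α = 0.05).

## Worked example

```r
library(pris)

co <- generate_cohort(cohort_config(n_patients = 110, seed = 42))
co
#> <slit_cohort> 110 patients (101 completers)
#>   spt: 304 rows | ige: 414 rows | vas: 3788 rows

compute_pris(patient_record(co, "P001"))
#> <pris_breakdown>
#>   age_score              3
#>   clinical_score         6
#>   onset_score            3
#>   sensitization_score   16
#>   exposure_score        12
#>   ratio_score            8
#>   crd_score              6
#>   dominance_score       15
#>   total                 69

bundle <- run_pipeline(co, output_dir = "report")
bundle$regression
#> R = 0.640; F(1,99) = 68.855; p = 5.5e-13; slope = 1.1865
bundle$strata_anova$group_means
#>   group  n     mean        sd
#> 1    Q1 26 78.96400 14.936528
#> 2    Q2 67 65.64334 14.968764
#> 3    Q3  8 48.82327  9.548533
```

Patient `P001` (an adult with asthma, late onset, but monosensitized
with one clearly dominant allergen) scores 69 — second quartile, "high
improvement expected". At cohort level PRIS explains ΔMSS-24(%) with
R = 0.64, and mean improvement falls monotonically across the PRIS
strata (≈79 % in Q1 down to ≈49 % in Q3) — patients with higher scores
improve more. `run_pipeline()` writes all per-patient tables, a
`metrics.json` with every statistic, and the four standard figures.

A command-line wrapper with subcommands
`simulate / screen / dominance / score / outcomes / validate / run`
ships at `inst/cli/pris-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pris-cli.R",package="pris"))')" \
    simulate --n 110 --seed 42 --out cohort/
```

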