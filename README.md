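# mymindd

An R toolkit for the **MY-MINDD** dietary index — the Malaysian adaptation of
the MIND (Mediterranean–DASH Intervention for Neurodegenerative Delay) diet —
and for the epidemiological pipeline used to validate such an index against
mild cognitive impairment (MCI) in an older-adult cohort.

It is written for nutritional epidemiologists and biostatisticians who need

* reproducible **banded diet-index scoring** from food-frequency data,
* a **Petersen-style MCI classifier** (RAVLT z-score criterion),
* a **seeded synthetic cohort generator** calibrated to published cohort
  marginals, so the whole pipeline is testable without any participant data,
* the standard **validation statistics**: quantile score groups, descriptive
  tables, ANOVA / Mann–Whitney / chi-square / Pearson correlation /
  Kolmogorov–Smirnov comparisons, multiple imputation with Rubin pooling, and
  three-block hierarchical binary logistic regression reported as odds ratios
  with Wald 95% confidence intervals.

## The index

MY-MINDD scores 11 food groups — 7 brain-healthy (whole grains, green leafy
vegetables, other vegetables, flavonoid-rich fruits, deep-sea fish, legumes
and soy, poultry) and 4 unhealthy (desserts/sweetened *kuih*/beverages,
butter/margarine, red meat, fried/fast foods). Each component earns
0 / 0.5 / 1 points from consumption-frequency bands, so the total
`S = Σ_j s_j ∈ [0, 11]` in half-point steps; higher is better adherence.
The original 15-component MIND table (berries, olive oil, wine, cheese, …)
ships alongside it. All bands are stored as explicit half-open partitions of
`[0, ∞)` servings/week (per-day ×7, per-month ÷4.348) and are validated for
gaps, overlaps and polarity monotonicity at load time.

The association model is a hierarchical binary logistic regression of MCI on
quantile groups T1…T4 of the score (T1 reference):

* **Model 1** + age, education years, household income, smoking;
* **Model 2** + IADL, GDS-15, hypertension, diabetes;
* **Model 3** + BMI,

with `OR = exp(β̂)` and Wald CIs `exp(β̂ ± 1.96·SE)`, all blocks fitted on the
common complete-case sample.

## Worked example

Score one participant:

```r
library(mymindd)
rules <- load_scoring_table("MY-MINDD")
p <- intake_profile("p01", frequencies = list(
  whole_grains     = frequency_value(1,   "per_day"),
  green_leafy      = frequency_value(1.5, "per_day"),
  other_vegetables = frequency_value(2,   "per_day"),
  flavonoid_fruits = frequency_value(1,   "per_week"),
  deep_sea_fish    = frequency_value(3,   "per_week"),
  legumes_soy      = frequency_value(2,   "per_week"),
  poultry          = frequency_value(2,   "per_week"),
  desserts_kuih    = frequency_value(1,   "per_day"),
  butter_margarine = frequency_value(1,   "per_day"),
  red_meat         = frequency_value(5,   "per_week"),
  fried_fast_foods = frequency_value(2,   "per_week")))
res <- score_profile(rules, p)
res$component_scores
#>     whole_grains      green_leafy other_vegetables flavonoid_fruits
#>              0.5              1.0              0.5              0.5
#>    deep_sea_fish      legumes_soy          poultry    desserts_kuih
#>              1.0              0.5              1.0              0.0
#> butter_margarine         red_meat fried_fast_foods
#>              0.5              0.5              0.5
res$total
#> [1] 6.5
```

Half a point for 1/day of whole grains (the 1-point band needs ≥ 3/day), a
zero for daily sweetened desserts (≥ 7/week), full points for fish and
poultry in their top bands: 6.5 of 11.

Simulate a cohort at the packaged published marginals and fit the three
blocks:

```r
co <- generate_cohort(cohort_config(n = 810, seed = 1))
fit_hierarchical_logistic(co)
#> -- Model3  logLik = -439.694 --
#>           term    or ci_lower ci_upper       p
#>  score_groupT2 0.604    0.394    0.928 2.1e-02
#>  score_groupT3 0.758    0.492    1.167 2.1e-01
#>  score_groupT4 0.802    0.468    1.373 4.2e-01
#>   hypertension 2.250    1.621    3.122 1.2e-06
#>  ...
```

A single n = 810 replicate is noisy (the generating top-group OR is 0.43);
the acceptance script below shows the median over 200 seeded replicates
recovering it.

## Command line

```sh
Rscript exec/mymindd simulate --seed 1 --n 810 --out cohort.csv
Rscript exec/mymindd score    --in cohort.csv --out scores.csv
Rscript exec/mymindd classify --in cohort.csv --out classified.csv
Rscript exec/mymindd analyze  --cohort cohort.csv --out report/
Rscript exec/mymindd report   --in report/
```

Every artifact is byte-reproducible from `(inputs, config, seed)`.

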