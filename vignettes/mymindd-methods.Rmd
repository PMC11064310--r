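---
title: "Methods: scoring, simulation and validation of the MY-MINDD index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, simulation and validation of the MY-MINDD index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mymindd)
```

This vignette is the package's own account of its science: what the scoring
rules encode, what the synthetic cohort does and does not emulate, how the
validation pipeline is specified numerically, and where genuinely open
design choices were settled.

## 1. The scoring model

A diet index of this family assigns each food-group component a score
$s_j \in \{0, 0.5, 1\}$ from consumption-frequency bands and totals them,
$S=\sum_j s_j$. MY-MINDD has 11 components (7 healthy, 4 unhealthy,
maximum 11); the original MIND table has 15 (including the categorical
olive-oil component and the deliberately non-monotone wine component).

**Canonical unit.** Published band anchors mix per-day, per-week and
per-month units. Everything is normalized to servings/week: per-day
amounts ×7, per-month ÷4.348 (a 30.44-day month). Band thresholds are
stored already normalized, as exact constants; comparisons are plain double
comparisons against those constants, with no floating tolerance.

**Band topology.** The published tables anchor bands but leave small gaps
(e.g. poultry's 0.5 column reads "1 serving/week" while the 1-point band
starts at 2). Each component's bands are therefore stored as an explicit
half-open partition of $[0,\infty)$: literal "1 serving/week" anchors widen
to $[1, 2)$, desserts' unhealthy bands resolve to $[0,5), [5,7), [7,\infty)$,
butter/margarine's middle band is the closed $[7, 14]$ servings
(1–2 Tbsp/day), and so on. The loader *proves* the partition property (start
closed at 0, adjacent bands share a boundary with complementary closure,
last band unbounded) and rejects tables that gap or overlap, naming the
component. It also enforces polarity monotonicity — points non-decreasing in
intake for healthy components, non-increasing for unhealthy — except for
wine, which is exempt by design: zero intake ("never") and more than one
glass/day both score 0, with $\,(0,6]\to 0.5$ and $(6,7]\to 1$ servings/week
between.

**Missing intake** never silently scores 0: the default policy refuses to
total an incomplete profile and flags it; a treat-as-zero policy is opt-in.
Silent zeros would bias totals downward in exactly the direction that
inflates apparent associations.

## 2. MCI classification

The classifier operationalizes the Petersen-style criteria: MCI requires
*all* of (i) objective memory impairment — RAVLT z-score
$z=(x-\mu_{\mathrm{ref}})/\sigma_{\mathrm{ref}} \le -1.5$; (ii) intact
instrumental activities of daily living; (iii) subjective memory complaint;
(iv) preserved global function — MMSE at or above a cutoff; (v) no dementia
diagnosis (dementia cases are returned as a separate `excluded-dementia`
level).

Choices the source description leaves open, and the defaults taken here
(all configurable via `mci_criteria()`):

* **Reference population** for the z-score: the cohort's non-dementia
  sample, with mean/SD computed *once* before classification (never
  re-estimated from the classified subset, so classification is idempotent);
  external norms can be supplied.
* **Global function**: MMSE ≥ 19.
* **IADL intact**: the scale maximum observed in the data (14 with the
  packaged generator).
* **Depressive-symptom dichotomy**: GDS-15 ≥ 5, the standard screen.
* **Which RAVLT subscore** feeds the rule is not derivable from the data
  model; the single `ravlt` column is used.

A known, deliberate consequence: with cohort-level RAVLT moments like
4.1 ± 3.3 the 1.5-SD threshold lies below zero, and since RAVLT is bounded
at 0 the criterion is rarely met. This is a faithful rendering of the rule
as stated — the instrument scale on which the original 1.5-SD rule operated
is simply not recoverable. The validation pipeline therefore regresses on
the simulation truth (`true_mci`), and `classify_cohort()` exposes
`classified_mci` as the separate pipeline output it is.

## 3. What the synthetic cohort emulates

The generator's defaults *are* the published marginals of the pooled
Malaysian cohort (n = 810 = 579 + 231): age 67.9 ± 4.7 truncated at 60,
48.1% male, 65.7% Malay, education 7.7 ± 4.2 years, household income
RM 1724.1 ± 2096.7, BMI 25.6 ± 4.2, hypertension 37.3%, diabetes 20.1%,
hyperlipidemia 31.6%, smoking 26.3%, depressive symptoms 7.8%,
IADL 13.0 ± 1.5 on [0, 14], MCI prevalence 30.2%, and status-conditional
neuropsychological moments (e.g. RAVLT 4.6 ± 3.5 non-MCI vs 2.9 ± 2.4 MCI).

Numerical choices:

* **Truncated normals with moment-matched locations.** Bounded instruments
  are drawn from truncated normals whose *location is solved* so the
  truncated mean equals the published mean (e.g. a naive N(2.9, 2.4)
  truncated at 0 would have mean ≈ 3.4; the solver shifts the location down
  until the truncated mean is 2.9). This reconciles instrument bounds with
  the published moments; the realized SD is slightly below nominal near a
  bound, a conscious trade.
* **Income** is log-normal by moment matching (the published SD exceeds the
  mean; a symmetric model is untenable).
* **GDS-15** is binomial(15, p) with p solved so P(score ≥ 5) = 7.8%.
* **Intakes** are gamma-distributed (shape 1.5 — right-skewed, as
  food-frequency data are) with the scale of each component *calibrated by
  root-finding* so the expected 0/0.5/1 component score equals the published
  component-score mean (0.12 whole grains … 0.92 butter/margarine). The
  expected score is monotone in the gamma scale (stochastic ordering), so
  the root is unique.
* **Outcome model.** MCI is Bernoulli with
  $\mathrm{logit}\,P = \alpha + \sum_k \beta_k x_k$, where $\beta_k$ are the
  natural logs of the packaged fully adjusted odds ratios (T2 0.52, T3 0.50,
  T4 0.43, age 1.04/yr, education 0.93/yr, income 1.00/RM, smoking 0.91,
  IADL 0.98, GDS 1.20/point, hypertension 1.99, diabetes 1.19,
  BMI 1.22/kg·m⁻²) and $\alpha$ is solved by `uniroot` (tolerance 1e-6) so
  the marginal prevalence is 30.2%.
* **RNG contract.** Every cell is a pure function of
  (seed, participant id, purpose, draw) through a splitmix-style 32-bit
  counter hash; draws are inverse-CDF transforms of the resulting uniform.
  Appending rows or permuting row order never changes existing values, and
  nothing touches R's global RNG.

What it deliberately does **not** emulate: covariate–covariate correlation
(marginals only are published; independence is a modeling choice), the real
tertile boundaries of the study sample, instrument granularity of the
continuous test scores (kept continuous so means calibrate exactly), and
selection/measurement processes of the original studies. A green calibration
test therefore establishes that the *pipeline recovers what the generator
encodes* — not that the generator reproduces the real cohort's joint
distribution.

## 4. The validation pipeline

* **Score groups**: type-7 empirical quantiles at $1/k,\dots,(k-1)/k$; ties
  at a boundary go to the lower group. The source nomenclature says
  "tertiles" but prints four groups; the default is $k=4$, configurable.
* **Comparisons**: one-way equal-variance ANOVA across groups; two-sided
  Mann–Whitney for two groups (exact when combined n ≤ 20 without ties,
  otherwise tie-corrected normal approximation, no continuity correction);
  Pearson chi-square without continuity correction; Pearson product-moment
  correlation with the t-test p.
* **Normality screen**: one-sample Kolmogorov–Smirnov against a normal with
  the sample's own mean/SD (no Lilliefors correction; used as a screen, not
  an inference).
* **Hierarchical logistic**: all blocks fitted by `glm` maximum likelihood
  on the *intersection* of complete cases, so log-likelihoods are nested and
  comparable; Wald CIs with z = 1.96; two-sided Wald p; no multiple-testing
  correction anywhere (none is applied in this literature's reporting);
  separation is detected (convergence failure or |β̂| > 15) and reported as
  an error naming the covariate. Covariate coding: smoking ever/never 0/1,
  GDS-15 and income continuous, BMI continuous kg/m² in Model 3 (a
  categorical option exists via `bmi_category()`), hypertension/diabetes 0/1.
* **Missing data**: complete-case (logged), single mean/mode, or a compact
  chained-equations multiple imputation (linear-model draws for continuous
  variables, logistic draws for binary, 5 cycles, seeded) pooled by Rubin's
  rules.

## 5. Degenerate inputs and tie-breaks

Zero-SD distributions collapse to their (clamped) mean; empty profiles,
empty groups, constant correlation inputs, empty contingency margins,
fewer distinct scores than groups, entirely-missing variables and
unattainable target prevalences are all errors, raised before any output is
produced. Band boundaries are exact; quantile boundaries inherit type-7
interpolation.

## 6. Known limitations

* Cohort-level quantities of the real study (exact CIs, the r = 0.154-class
  correlations, real tertile cut points) are not reproducible without the
  raw data and are *not* claimed; the package validates by parameter
  recovery on its own stated world instead.
* The income odds ratio is 1.00 per RM at the published rounding; the
  original income scaling is not recoverable, so no claim is made beyond
  that rounding.
* The Wald intervals are first-order; at n = 810 with ~30% prevalence the
  small-sample bias of the group-indicator OR is visible (a few percent
  toward the null in the median over replicates), which is inherent to the
  estimator, not to the generator.
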