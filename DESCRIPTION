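Package: mymindd
Title: MY-MINDD Dietary Index Scoring and MCI Association Toolkit
Version: 0.1.0
Authors@R:
    person("Analysis", "Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Malaysian adaptation of the MIND
    (Mediterranean-DASH Intervention for Neurodegenerative Delay) dietary
    index (MY-MINDD, 11 food-group components) together with the original
    15-component MIND index as banded scoring tables, a Petersen-style
    mild cognitive impairment (MCI) classifier built on a RAVLT z-score
    criterion, a seeded synthetic cohort generator calibrated to published
    marginals of a pooled Malaysian ageing cohort, and the validation
    pipeline used in nutritional epidemiology: quantile score groups,
    descriptive and inferential group comparisons (ANOVA, Mann-Whitney,
    chi-square, Pearson correlation, Kolmogorov-Smirnov), multiple
    imputation with Rubin pooling, and three-block hierarchical binary
    logistic regression reported as odds ratios with Wald confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
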