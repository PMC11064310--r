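# Scoring rules: unit normalization, band lookup, profile totals,
# table loading and validation.

mymindd_rules <- load_scoring_table("MY-MINDD")
mind_rules <- load_scoring_table("MIND-original")

test_that("frequency normalization follows the week convention", {
  expect_equal(normalize_frequency(frequency_value(1, "per_day")), 7)
  expect_equal(normalize_frequency(frequency_value(14, "per_week")), 14)
  expect_equal(round(normalize_frequency(frequency_value(1, "per_month")), 2),
               0.23)
  expect_equal(normalize_frequency(c(1, 2), c("per_day", "per_week")),
               c(7, 2))
  expect_error(normalize_frequency(1, "per_year"), "unknown unit")
  expect_error(frequency_value(-1, "per_day"), "non-negative")
})

test_that("component scoring hits the printed bands", {
  expect_equal(score_component(mymindd_rules, frequency_value(3, "per_day"),
                               "whole_grains"), 1)
  expect_equal(score_component(mymindd_rules, frequency_value(7, "per_week"),
                               "red_meat"), 0)
  expect_equal(score_component(mymindd_rules, frequency_value(1, "per_week"),
                               "flavonoid_fruits"), 0.5)
  expect_equal(score_component(mymindd_rules, frequency_value(0, "per_week"),
                               "legumes_soy"), 0)
  expect_equal(score_component(mind_rules, frequency_value(2, "per_day"),
                               "wine"), 0)
  expect_equal(score_component(mind_rules, "primary", "olive_oil"), 1)
  expect_true(is.na(score_component(mymindd_rules, NA, "poultry")))
  expect_error(score_component(mind_rules, "sometimes", "olive_oil"),
               "unknown category")
  expect_error(score_component(mymindd_rules, frequency_value(1, "per_day"),
                               "durian"), "unknown component")
})

test_that("profile totals reach the ceiling, the floor and the midpoint", {
  best <- score_profile(mymindd_rules, profile_at(mymindd_rules, "best"))
  expect_equal(best$total, 11)
  worst <- score_profile(mymindd_rules, profile_at(mymindd_rules, "worst"))
  expect_equal(worst$total, 0)
  mid <- score_profile(mymindd_rules, profile_at(mymindd_rules, "middle"))
  expect_equal(mid$total, 5.5)
  best15 <- score_profile(mind_rules, profile_at(mind_rules, "best"))
  expect_equal(best15$total, 15)
  expect_error(score_profile(mymindd_rules, intake_profile("x")), "empty")
})

test_that("missing components refuse to total unless configured otherwise", {
  p <- profile_at(mymindd_rules, "best")
  p$frequencies$poultry <- NA
  refused <- score_profile(mymindd_rules, p)
  expect_true(refused$incomplete)
  expect_true(is.na(refused$total))
  expect_equal(refused$missing_components, "poultry")
  zeroed <- score_profile(mymindd_rules, p, missing = "zero")
  expect_equal(zeroed$total, 10)
  expect_false(zeroed$incomplete)
})

test_that("rule-table loader validates structure", {
  expect_equal(length(mymindd_rules$components), 11)
  pol <- table(vapply(mymindd_rules$components, `[[`, "", "polarity"))
  expect_equal(unname(pol[["healthy"]]), 7)
  expect_equal(unname(pol[["unhealthy"]]), 4)
  expect_equal(length(mind_rules$components), 15)
  expect_error(load_scoring_table("NO-SUCH-DIET"), "unknown rule set")

  overlap <- tempfile(fileext = ".json")
  writeLines('{
    "name": "bad", "components": [{
      "id": "x", "polarity": "healthy", "input_kind": "frequency",
      "bands": [
        {"lower": 0, "upper": 2, "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 1, "upper": 3, "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 3, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]}]}', overlap)
  expect_error(load_scoring_table(overlap), "x")

  short <- tempfile(fileext = ".json")
  writeLines('{
    "name": "MY-MINDD", "components": [{
      "id": "x", "polarity": "healthy", "input_kind": "frequency",
      "bands": [
        {"lower": 0, "upper": 1, "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 1, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]}]}', short)
  expect_error(load_scoring_table(short), "11 components")
})

test_that("every intake falls in exactly one band (partition property)", {
  grid <- c(seq(0, 100, by = 0.25), 0.23, 1/3, 6.999, 7.001)
  for (rules in list(mymindd_rules, mind_rules)) {
    for (cp in rules$components) {
      if (cp$input_kind != "frequency") next
      for (x in grid) {
        hits <- sum(vapply(cp$bands, function(b) {
          lo <- if (b$lower_closed) x >= b$lower else x > b$lower
          hi <- if (b$upper_closed) x <= b$upper else x < b$upper
          lo && hi
        }, TRUE))
        if (hits != 1L)
          fail(sprintf("%s/%s: %g falls in %d bands", rules$name,
                       cp$component_id, x, hits))
      }
    }
  }
  succeed()
})

test_that("random profiles respect the total-score bound and half-point grid", {
  set.seed(11)
  for (i in 1:50) {
    freqs <- lapply(mymindd_rules$components, function(cp)
      stats::rexp(1, 1 / 5))
    names(freqs) <- names(mymindd_rules$components)
    res <- score_profile(mymindd_rules,
                         intake_profile(i, frequencies = freqs))
    expect_gte(res$total, 0)
    expect_lte(res$total, mymindd_rules$max_total)
    expect_equal(res$total %% 0.5, 0)
  }
})

test_that("cohort scoring matches profile scoring and keeps column order", {
  df <- data.frame(id = 1:3)
  for (cp in mymindd_rules$components)
    df[[paste0(cp$component_id, "_wk")]] <- c(0, 1.5, 25)
  sc <- score_cohort(df, mymindd_rules)
  expect_equal(names(sc)[1], "id")
  expect_equal(names(sc)[length(names(sc))], "diet_incomplete")
  for (cp in mymindd_rules$components) {
    col <- paste0("score_", cp$component_id)
    expect_equal(sc[[col]][2], brute_force_score(cp, 1.5), info = col)
  }
  # amount/unit column pairs normalize identically to _wk columns
  df2 <- data.frame(id = 1:2,
                    whole_grains_amount = c(3, 1),
                    whole_grains_unit = c("per_day", "per_week"))
  sc2 <- score_cohort(df2, mymindd_rules, missing = "zero")
  expect_equal(sc2$score_whole_grains, c(1, 0))
})
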