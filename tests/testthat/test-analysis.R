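# Analysis pipeline: grouping, descriptives, group comparisons,
# correlation, regression, normality screen.

test_that("quantile groups are balanced without ties, deterministic with them", {
  g <- assign_score_groups(1:8, k = 4)
  expect_equal(as.vector(table(g$group)), c(2, 2, 2, 2))
  expect_equal(levels(g$group), c("T1", "T2", "T3", "T4"))

  # hand enumeration: sorted (5,5,5,6,7,8,8,9); type-7 quantiles at
  # 0.25/0.5/0.75 are 5, 6.5, 8; ties at a boundary drop to the lower group
  scores <- c(5, 5, 5, 6, 7, 8, 8, 9)
  bounds <- stats::quantile(scores, c(.25, .5, .75), type = 7, names = FALSE)
  oracle <- 1L + vapply(scores, function(s) sum(s > bounds), 0L)
  g2 <- assign_score_groups(scores, k = 4)
  expect_equal(as.integer(g2$group), oracle)
  expect_equal(as.vector(table(g2$group)), c(3, 1, 3, 1))

  expect_error(assign_score_groups(c(1, 1, 2), k = 4), "distinct")
  expect_error(assign_score_groups(1:8, k = 1), "k")
  # partition: sizes always sum to n
  set.seed(3)
  x <- sample(seq(0, 11, by = 0.5), 810, replace = TRUE)
  expect_equal(sum(table(assign_score_groups(x, 4)$group)), 810)
})

test_that("group descriptives reproduce counts, percents and moments", {
  status <- factor(c(rep("MCI", 245), rep("non-MCI", 565)),
                   levels = c("non-MCI", "MCI"))
  d <- data.frame(status = status, x = rep(1, 810))
  tab <- describe_groups(d, NULL, "status")
  mci_row <- tab[tab$level == "MCI" & tab$group == "All", ]
  expect_equal(round(mci_row$pct, 1), 30.2)
  expect_equal(mci_row$count, 245)

  # identity grouping equals the overall column
  d2 <- data.frame(y = rnorm(50))
  t_all <- describe_groups(d2, rep("G", 50), "y")
  expect_equal(t_all$mean[t_all$group == "All"],
               t_all$mean[t_all$group == "G"])
  # constant variable, forced continuous, has sd 0
  d3 <- data.frame(z = rep(2.5, 30))
  tz <- describe_groups(d3, NULL, "z", continuous = "z")
  expect_equal(tz$sd[1], 0)
  expect_equal(tz$mean[1], 2.5)
  expect_error(describe_groups(d2, factor(rep("a", 50),
                                          levels = c("a", "b")), "y"),
               "empty group")
  expect_error(describe_groups(d2, rep("G", 50), "missing_var"), "missing_var")
})

test_that("continuous comparisons: ANOVA null and Mann-Whitney oracle", {
  x <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  an <- compare_continuous(data.frame(v = x), g, "v", test = "anova")
  expect_equal(an$statistic, 0)
  expect_equal(an$p, 1)

  # complete separation: U = 0 for the lower group listed second
  sep <- compare_continuous(data.frame(v = c(10, 11, 12, 1, 2, 3)),
                            c("hi", "hi", "hi", "lo", "lo", "lo"),
                            "v", test = "mann_whitney")
  expect_true(sep$statistic %in% c(0, 9))  # orientation: all pairs one-sided
  expect_equal(min(sep$statistic, 9 - sep$statistic), 0)

  # U equals the count-of-pairs oracle on a small two-group example
  x1 <- c(1.2, 3.4, 2.2); x2 <- c(0.5, 2.9, 4.1)
  u_oracle <- sum(outer(x1, x2, ">")) + 0.5 * sum(outer(x1, x2, "=="))
  mw <- compare_continuous(data.frame(v = c(x1, x2)),
                           rep(c("a", "b"), each = 3), "v", "mann_whitney")
  expect_equal(unname(mw$statistic), u_oracle)
  expect_error(compare_continuous(data.frame(v = 1:4),
                                  c("a", "a", "b", "c"), "v",
                                  "mann_whitney"), "exactly 2")
  expect_error(compare_continuous(data.frame(v = 1:3),
                                  c("a", "a", "b"), "v", "anova"), ">= 2")
})

test_that("chi-square matches independence and the published hypertension split", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- compare_categorical(variable = even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1)
  # hypertension yes/no by status: (176, 389) vs (126, 119)
  htn <- matrix(c(176, 126, 389, 119), nrow = 2)
  r2 <- compare_categorical(variable = htn)
  expect_lt(r2$p, 0.001)
  expect_error(compare_categorical(variable = matrix(c(0, 0, 3, 4), 2)),
               "empty margin")
})

test_that("Pearson correlation: exact lines and the hand-computed example", {
  d <- data.frame(diet_total = 1:10, up = 2 * (1:10) + 1, down = -(1:10))
  r <- correlate_score_cognition(d, c("up", "down"))
  expect_equal(r$r, c(1, -1))
  # (1,2),(2,1),(3,4),(4,3),(5,5): direct product-moment formula gives 0.8
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_oracle, 0.8)
  r2 <- correlate_score_cognition(data.frame(diet_total = x, t = y), "t")
  expect_equal(r2$r, r_oracle)
  expect_error(correlate_score_cognition(
    data.frame(diet_total = rep(1, 5), t = 1:5), "t"), "constant")
})

test_that("normality screen matches the ECDF-gap oracle", {
  v <- c(1.1, 2.3, 2.9, 4.2, 8.0)
  ks <- normality_check(v)
  sorted <- sort(v)
  theo <- stats::pnorm(sorted, mean(v), stats::sd(v))
  d_oracle <- max(pmax(abs(theo - (seq_along(v) - 1) / 5),
                       abs(theo - seq_along(v) / 5)))
  expect_equal(ks$statistic, d_oracle)
  # gross violation is flagged at n = 1000
  bimodal <- c(rnorm(500, -4, 0.3), rnorm(500, 4, 0.3))
  expect_lt(normality_check(bimodal)$p, 1e-6)
  expect_error(normality_check(c(1, 2)), ">= 5")
  expect_error(normality_check(rep(3, 10)), "constant")
})

test_that("logistic blocks are ML fits with Wald intervals, nested logLik", {
  co <- generate_cohort(cohort_config(n = 810, seed = 10))
  fits <- fit_hierarchical_logistic(co)
  expect_named(fits, c("Model1", "Model2", "Model3"))
  ll <- vapply(fits, attr, 0, "logLik")
  expect_true(ll[["Model2"]] >= ll[["Model1"]])
  expect_true(ll[["Model3"]] >= ll[["Model2"]])
  m3 <- fits[["Model3"]]
  expect_equal(m3$or, exp(m3$estimate))
  expect_true(all(m3$ci_lower <= m3$or & m3$or <= m3$ci_upper))
  expect_error(fit_hierarchical_logistic(
    co, specs = list(A = c("age", "bmi"), B = "age")), "nested")
  # complete-case bookkeeping
  co$age[1:7] <- NA
  fits2 <- fit_hierarchical_logistic(co)
  expect_equal(attr(fits2, "n_used"), 803)
  expect_equal(attr(fits2, "n_dropped"), 7)
  # separation is reported, naming a covariate
  co3 <- co
  co3$sep <- as.numeric(co3$true_mci)
  expect_error(fit_hierarchical_logistic(co3, specs = list(M = "sep")),
               "separation")
})

test_that("Model-3 fit on a 20k cohort recovers every generating OR", {
  cfg <- cohort_config(n = 20000, seed = 42)
  co <- generate_cohort(cfg)
  m3 <- fit_hierarchical_logistic(co)[["Model3"]]
  gen <- cfg$outcome_or
  for (term in names(gen)) {
    row <- m3[m3$term == term, ]
    expect_equal(nrow(row), 1, info = term)
    expect_lt(abs(row$or - gen[[term]]) / gen[[term]], 0.10)
    # and the log-odds estimate sits within 3 Wald SEs of the truth
    expect_lt(abs(row$estimate - log(gen[[term]])), 3 * row$se)
  }
})

test_that("per-component contrast table has 11 + 1 rows and additive means", {
  co <- generate_cohort(cohort_config(n = 400, seed = 12))
  tab <- compare_components(co)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$component[12], "diet_total")
  comp <- tab[1:11, ]
  expect_equal(sum(comp$mean_mci), tab$mean_mci[12], tolerance = 1e-10)
  expect_equal(sum(comp$mean_non_mci), tab$mean_non_mci[12], tolerance = 1e-10)
  # identical score distributions across groups give p ~ 1
  d <- data.frame(score_a = rep(c(0, 0.5, 1), 20),
                  diet_total = rep(c(0, 0.5, 1), 20),
                  true_mci = rep(c(TRUE, FALSE), 30))
  t2 <- compare_components(d)
  expect_gt(min(t2$p), 0.9)
})
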