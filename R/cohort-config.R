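# Packaged synthetic-cohort configuration: the published marginals of the
# pooled Malaysian ageing sample (LRGS-TUA 579 + FRGS 231, n = 810) that the
# generator targets, plus the fully adjusted outcome model odds ratios.

# Component-score target means ("Total" column of the component comparison
# table); these drive the gamma intake calibration.
.default_score_targets <- c(
  whole_grains     = 0.12,
  green_leafy      = 0.73,
  other_vegetables = 0.48,
  flavonoid_fruits = 0.49,
  deep_sea_fish    = 0.57,
  legumes_soy      = 0.30,
  poultry          = 0.54,
  desserts_kuih    = 0.77,
  butter_margarine = 0.92,
  red_meat         = 0.91,
  fried_fast_foods = 0.59
)

# Fully adjusted (Model 3) odds ratios; log() of these are the generating
# log-odds coefficients. Income OR is 1.00 (per RM), i.e. a null effect.
.default_outcome_or <- c(
  score_groupT2    = 0.52,
  score_groupT3    = 0.50,
  score_groupT4    = 0.43,
  age              = 1.04,
  education_years  = 0.93,
  household_income = 1.00,
  smoking          = 0.91,
  iadl             = 0.98,
  gds15            = 1.20,
  hypertension     = 1.99,
  diabetes         = 1.19,
  bmi              = 1.22
)

# Status-conditional neuropsychological test moments (mean, sd) and
# instrument bounds.
.default_neuro_model <- list(
  mmse         = list(non_mci = c(25.4, 4.1),  mci = c(23.1, 2.9),  bounds = c(0, 30)),
  digit_span   = list(non_mci = c(8.4, 2.4),   mci = c(8.2, 2.4),   bounds = c(0, Inf)),
  ravlt        = list(non_mci = c(4.6, 3.5),   mci = c(2.9, 2.4),   bounds = c(0, Inf)),
  digit_symbol = list(non_mci = c(6.0, 2.8),   mci = c(4.7, 2.4),   bounds = c(0, Inf)),
  vr1          = list(non_mci = c(26.4, 8.2),  mci = c(22.4, 7.5),  bounds = c(0, Inf)),
  vr2          = list(non_mci = c(19.3, 11.7), mci = c(12.9, 10.4), bounds = c(0, Inf))
)

#' Synthetic cohort configuration
#'
#' Packaged defaults reproduce the published marginals of the pooled cohort:
#' age 67.9 +/- 4.7 (truncated at 60), 48.1% male, 65.7% Malay, education
#' 7.7 +/- 4.2 years, household income RM 1724.1 +/- 2096.7 (log-normal by
#' moment matching), BMI 25.6 +/- 4.2, hypertension 37.3%, diabetes 20.1%,
#' hyperlipidemia 31.6%, smoking 26.3%, depressive symptoms 7.8% (GDS-15
#' binomial with solved item probability), IADL 13.0 +/- 1.5 on [0, 14];
#' gamma intakes calibrated so expected component scores match the published
#' means; outcome model with log-OR coefficients and intercept solved for
#' 30.2% MCI prevalence. Truncated-normal locations are moment-matched so
#' the *truncated* means hit the published values.
#'
#' @param n Cohort size (default 810, the pooled sample).
#' @param seed Master seed; every cell of the generated table is a pure
#'   function of (config, seed).
#' @param prevalence Target marginal MCI prevalence (default 0.302).
#' @param score_targets Named component-score means for intake calibration.
#' @param outcome_or Named odds ratios for the generating outcome model.
#' @param intake_shape Gamma shape for intake distributions.
#' @param rules Scoring rule set used to score generated intakes.
#' @return A `cohort_config` list with all solved parameters embedded.
#' @export
cohort_config <- function(n = 810, seed = 1, prevalence = 0.302,
                          score_targets = .default_score_targets,
                          outcome_or = .default_outcome_or,
                          intake_shape = 1.5,
                          rules = load_scoring_table("MY-MINDD")) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be in (0,1)", call. = FALSE)
  covs <- list(
    age       = list(mean = 67.9, sd = 4.7, lower = 60, upper = Inf),
    education = list(mean = 7.7, sd = 4.2, lower = 0, upper = Inf),
    bmi       = list(mean = 25.6, sd = 4.2, lower = 10, upper = Inf),
    iadl      = list(mean = 13.0, sd = 1.5, lower = 0, upper = 14)
  )
  for (nm in names(covs)) {
    cv <- covs[[nm]]
    if (cv$sd <= 0) stop("sd for ", nm, " must be > 0", call. = FALSE)
    covs[[nm]]$mu <- truncnorm_mu_for_mean(cv$mean, cv$sd, cv$lower, cv$upper)
  }
  prev_binary <- c(male = 0.481, malay = 0.657, hypertension = 0.373,
                   diabetes = 0.201, hyperlipidemia = 0.316, smoking = 0.263,
                   dementia = 0)
  if (any(prev_binary < 0 | prev_binary > 1))
    stop("binary prevalences must lie in [0,1]", call. = FALSE)
  income <- lnorm_moment_match(1724.1, 2096.7)
  gds_p <- binom_tail_solve(0.078, size = 15, cutoff = 5)
  intake <- calibrate_intake_model(rules, score_targets, shape = intake_shape)
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    prevalence = prevalence,
    covariates = covs,
    prev_binary = prev_binary,
    income = income,
    gds_p = gds_p,
    complaint_prob = c(mci = 0.90, non_mci = 0.25),
    intake = intake,
    score_total_target = 6.41,  # published mean total score of the pooled sample
    rules = rules,
    outcome_or = outcome_or,
    neuro = .default_neuro_model,
    source_studies = c("LRGS-TUA" = 579L, "FRGS" = 231L),
    k_groups = 4L
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n, ", seed =", x$seed,
      ", target prevalence =", x$prevalence, "\n")
  invisible(x)
}
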