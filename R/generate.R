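# Synthetic cohort generation: covariates, food-group intakes, diet scores,
# model-based MCI assignment, status-conditional neuropsych batteries, and
# missingness injection. All draws flow through id-indexed substreams
# (see rng.R), so output is a pure function of (config, seed) and appending
# rows never perturbs existing ones.

#' Generate a synthetic cohort
#'
#' Emulates the pooled ageing cohort the packaged defaults describe: draws
#' covariates from the configured marginals, gamma food-group intakes
#' calibrated to the published component-score means, scores them with the
#' configured rule set, assigns quantile score groups, simulates MCI from
#' the logistic outcome model (intercept solved for the target prevalence),
#' and fills the status-conditional neuropsychological battery.
#'
#' @param cfg A [cohort_config()].
#' @param seed Master seed; defaults to `cfg$seed`.
#' @return Data.frame, one row per participant, with covariates, `<id>_wk`
#'   intake columns, `score_<id>` component scores, `diet_total`,
#'   `score_group`, `true_mci`, neuropsych scores and functional flags.
#'   The solved outcome-model intercept is attached as attribute
#'   `outcome_intercept`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = cfg$seed) {
  if (!inherits(cfg, "cohort_config")) stop("`cfg` must be a cohort_config",
                                            call. = FALSE)
  n <- cfg$n
  id <- seq_len(n)
  u <- function(purpose) substream_uniform(seed, id, purpose)

  cv <- cfg$covariates
  d <- data.frame(
    id = id,
    age = qtruncnorm(u(.purpose[["age"]]), cv$age$mu, cv$age$sd,
                     cv$age$lower, cv$age$upper),
    sex = factor(ifelse(u(.purpose[["sex"]]) < cfg$prev_binary[["male"]],
                        "male", "female"), levels = c("female", "male")),
    ethnicity = factor(ifelse(u(.purpose[["ethnicity"]]) < cfg$prev_binary[["malay"]],
                              "malay", "non_malay"),
                       levels = c("malay", "non_malay")),
    education_years = qtruncnorm(u(.purpose[["education"]]), cv$education$mu,
                                 cv$education$sd, cv$education$lower,
                                 cv$education$upper),
    household_income = stats::qlnorm(u(.purpose[["income"]]),
                                     cfg$income[["meanlog"]],
                                     cfg$income[["sdlog"]]),
    bmi = qtruncnorm(u(.purpose[["bmi"]]), cv$bmi$mu, cv$bmi$sd,
                     cv$bmi$lower, cv$bmi$upper),
    hypertension = as.integer(u(.purpose[["hypertension"]]) <
                                cfg$prev_binary[["hypertension"]]),
    diabetes = as.integer(u(.purpose[["diabetes"]]) <
                            cfg$prev_binary[["diabetes"]]),
    hyperlipidemia = as.integer(u(.purpose[["hyperlipidemia"]]) <
                                  cfg$prev_binary[["hyperlipidemia"]]),
    smoking = as.integer(u(.purpose[["smoking"]]) < cfg$prev_binary[["smoking"]]),
    gds15 = stats::qbinom(u(.purpose[["gds15"]]), 15, cfg$gds_p),
    iadl = round(qtruncnorm(u(.purpose[["iadl"]]), cv$iadl$mu, cv$iadl$sd,
                            cv$iadl$lower, cv$iadl$upper)),
    dementia = u(.purpose[["dementia"]]) < cfg$prev_binary[["dementia"]]
  )

  for (j in seq_len(nrow(cfg$intake))) {
    row <- cfg$intake[j, ]
    d[[paste0(row$component, "_wk")]] <-
      stats::qgamma(u(.purpose[["intake_base"]] + j),
                    shape = row$shape, scale = row$scale)
  }

  sc <- score_cohort(d, rules = cfg$rules)
  d <- cbind(d, sc[, setdiff(names(sc), "id")])

  grouping <- assign_score_groups(d$diet_total, k = cfg$k_groups)
  d$score_group <- grouping$group

  d <- assign_outcome(d, cfg$outcome_or, prevalence = cfg$prevalence,
                      seed = seed)
  d <- generate_neuropsych(d, cfg$neuro, seed = seed)

  p_complaint <- ifelse(d$true_mci, cfg$complaint_prob[["mci"]],
                        cfg$complaint_prob[["non_mci"]])
  d$memory_complaint <- u(.purpose[["memory_complaint"]]) < p_complaint
  d$depressive_symptoms <- as.integer(depressive_symptoms(d$gds15))
  d
}

#' Assign the simulated outcome from a logistic model
#'
#' `P(MCI) = plogis(intercept + sum(beta * x))` with `beta = log(OR)`; the
#' intercept is solved numerically (bisection via `uniroot`, tolerance 1e-6)
#' so the marginal expected prevalence equals `prevalence`. Bernoulli draws
#' come from each participant's substream.
#'
#' @param records Cohort table with `score_group` and the model covariates.
#' @param outcome_or Named odds ratios; `score_groupT2`..`score_groupTk`
#'   name the group indicator terms (first group is reference).
#' @param prevalence Target marginal prevalence.
#' @param seed Master seed.
#' @return `records` with a logical `true_mci` column and attributes
#'   `outcome_intercept` and `outcome_linpred`.
#' @export
assign_outcome <- function(records, outcome_or, prevalence = 0.302,
                           seed = 1) {
  if (!"score_group" %in% names(records))
    stop("score groups must be assigned before the outcome", call. = FALSE)
  beta <- log(outcome_or)
  eta <- numeric(nrow(records))
  for (term in names(beta)) {
    if (startsWith(term, "score_group")) {
      lev <- sub("^score_group", "", term)
      x <- as.numeric(records$score_group == lev)
    } else {
      if (!term %in% names(records))
        stop("outcome model term not in records: ", term, call. = FALSE)
      x <- as.numeric(records[[term]])
    }
    eta <- eta + beta[[term]] * x
  }
  lo <- -50; hi <- 50
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence ", prevalence, " unattainable for this linear predictor",
         call. = FALSE)
  intercept <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-6)$root
  p <- stats::plogis(intercept + eta)
  uo <- substream_uniform(seed, records$id, .purpose[["outcome"]])
  records$true_mci <- uo < p
  attr(records, "outcome_intercept") <- intercept
  attr(records, "outcome_linpred") <- eta
  records
}

#' Fill the neuropsychological battery conditional on MCI status
#'
#' Each test is a truncated normal at the instrument bounds (MMSE `[0, 30]`,
#' others `>= 0`) whose location is moment-matched so the truncated mean
#' equals the configured status-conditional target.
#'
#' @param records Cohort table with `true_mci` assigned.
#' @param neuro_model Per-test list of `non_mci`/`mci` `(mean, sd)` pairs
#'   and `bounds`.
#' @param seed Master seed.
#' @return `records` with one column per test.
#' @export
generate_neuropsych <- function(records, neuro_model, seed = 1) {
  if (!"true_mci" %in% names(records))
    stop("`true_mci` must be assigned before the neuropsych battery",
         call. = FALSE)
  mci <- records$true_mci
  for (j in seq_along(neuro_model)) {
    test <- names(neuro_model)[j]
    m <- neuro_model[[j]]
    uu <- substream_uniform(seed, records$id, .purpose[["neuro_base"]] + j)
    val <- numeric(nrow(records))
    for (grp in c("non_mci", "mci")) {
      sel <- if (grp == "mci") mci else !mci
      if (!any(sel)) next
      mean_sd <- m[[grp]]
      if (mean_sd[2] == 0) {
        val[sel] <- mean_sd[1]
      } else {
        mu <- truncnorm_mu_for_mean(mean_sd[1], mean_sd[2],
                                    m$bounds[1], m$bounds[2])
        val[sel] <- qtruncnorm(uu[sel], mu, mean_sd[2],
                               m$bounds[1], m$bounds[2])
      }
    }
    records[[test]] <- val
  }
  records
}

#' Inject missing-at-random cells
#'
#' Each selected cell is independently set to `NA` with probability `rate`,
#' using the per-(participant, variable) substream so the mask is a pure
#' function of `(seed, rate, variables)`.
#'
#' @param records Cohort table.
#' @param rate Missingness probability in `[0, 1)`.
#' @param variables Character vector of column names to perturb.
#' @param seed Master seed.
#' @return `records` with `NA`s injected.
#' @export
inject_missingness <- function(records, rate, variables, seed = 1) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("`rate` must lie in [0, 1)", call. = FALSE)
  absent <- setdiff(variables, names(records))
  if (length(absent))
    stop("unknown variables: ", paste(absent, collapse = ", "), call. = FALSE)
  if (rate == 0) return(records)
  for (k in seq_along(variables)) {
    v <- variables[[k]]
    uu <- substream_uniform(seed, records$id, .purpose[["missing_base"]] + k)
    records[[v]][uu < rate] <- NA
  }
  records
}
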