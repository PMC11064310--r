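# Hierarchical (nested-block) binary logistic regression reported as odds
# ratios with Wald 95% confidence intervals.

#' Default nested model specifications
#'
#' Three blocks sharing the score-group indicators (first group reference):
#' Model 1 adds sociodemographics (age, education years, household income,
#' smoking); Model 2 adds health and functional status (IADL, GDS-15,
#' hypertension, diabetes); Model 3 adds BMI.
#'
#' @return Named list of character vectors of covariate names; each block is
#'   a superset of the previous one.
#' @export
default_model_specs <- function() {
  m1 <- c("score_group", "age", "education_years", "household_income",
          "smoking")
  m2 <- c(m1, "iadl", "gds15", "hypertension", "diabetes")
  m3 <- c(m2, "bmi")
  list(Model1 = m1, Model2 = m2, Model3 = m3)
}

#' Fit nested logistic blocks
#'
#' Fits each block by maximum likelihood on the *common* complete-case
#' subsample (rows complete on the union of covariates), so log-likelihoods
#' are comparable across blocks. `score_group` expands to indicator terms
#' with the first level as reference. Reported per term: log-odds estimate,
#' SE, `OR = exp(est)`, Wald 95% CI `exp(est +/- 1.96 SE)`, two-sided Wald
#' p.
#'
#' @param cohort Data.frame.
#' @param specs Named list of covariate-name vectors, nested in order
#'   (default [default_model_specs()]).
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @return Named list of data.frames (`term`, `estimate`, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `p`), each with attributes `logLik` and `n`;
#'   class `hierarchical_logistic`.
#' @export
fit_hierarchical_logistic <- function(cohort, specs = default_model_specs(),
                                      outcome = "true_mci") {
  if (!outcome %in% names(cohort)) stop("no outcome column ", outcome,
                                        call. = FALSE)
  for (i in seq_along(specs)[-1L])
    if (!all(specs[[i - 1L]] %in% specs[[i]]))
      stop("model specs must be nested: ", names(specs)[i - 1L],
           " is not a subset of ", names(specs)[i], call. = FALSE)
  all_covs <- unique(unlist(specs))
  absent <- setdiff(all_covs, names(cohort))
  if (length(absent)) stop("covariates not in cohort: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  y <- cohort[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1) | is.na(y)))
    stop("outcome must be binary", call. = FALSE)
  used <- stats::complete.cases(cohort[, all_covs, drop = FALSE]) & !is.na(y)
  dat <- cohort[used, , drop = FALSE]
  dat$.y <- y[used]
  results <- list()
  for (label in names(specs)) {
    fml <- stats::reformulate(specs[[label]], response = ".y")
    # separation shows up as glm convergence warnings; they are muffled here
    # and re-raised as the explicit error below
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!fit$converged || any(abs(stats::coef(fit)[-1L]) > 15, na.rm = TRUE)) {
      worst <- names(which.max(abs(stats::coef(fit)[-1L])))
      stop("possible separation or non-convergence in ", label,
           " (covariate: ", worst, ")", call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    res <- data.frame(term = rownames(sm), estimate = est, se = se,
                      or = exp(est),
                      ci_lower = exp(est - 1.96 * se),
                      ci_upper = exp(est + 1.96 * se),
                      p = 2 * stats::pnorm(-abs(est / se)))
    rownames(res) <- NULL
    attr(res, "logLik") <- as.numeric(stats::logLik(fit))
    attr(res, "n") <- nrow(dat)
    results[[label]] <- res
  }
  structure(results, class = "hierarchical_logistic",
            n_used = nrow(dat), n_dropped = sum(!used))
}

#' @export
print.hierarchical_logistic <- function(x, digits = 3, ...) {
  cat("<hierarchical_logistic> n =", attr(x, "n_used"),
      "(", attr(x, "n_dropped"), "dropped )\n")
  for (label in names(x)) {
    cat("\n--", label, " logLik =",
        format(attr(x[[label]], "logLik"), digits = 6), "--\n")
    df <- x[[label]]
    df$or <- round(df$or, digits)
    df$ci_lower <- round(df$ci_lower, digits)
    df$ci_upper <- round(df$ci_upper, digits)
    df$p <- signif(df$p, 2)
    print(df[, c("term", "or", "ci_lower", "ci_upper", "p")],
          row.names = FALSE)
  }
  invisible(x)
}
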