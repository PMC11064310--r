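# Missing-data handling: complete-case, single mean/mode fill, and a small
# chained-equations multiple imputation with Rubin pooling.

#' Handle missing analysis variables
#'
#' * `complete_case` drops every row missing any of `variables` (count
#'   attached as attribute `n_dropped`).
#' * `single_mean_mode` fills continuous variables with the observed mean,
#'   categorical/low-cardinality ones with the mode.
#' * `multiple_imputation` produces `m` completed datasets by chained
#'   equations: each incomplete variable is regressed on the others
#'   (linear model with a normal residual draw for continuous variables,
#'   logistic draw for binary ones), cycling `cycles` times from a
#'   mean/mode start. Randomness is seeded and reproducible. Pool
#'   downstream estimates with [rubin_pool()].
#'
#' @param cohort Data.frame.
#' @param method One of `"complete_case"`, `"single_mean_mode"`,
#'   `"multiple_imputation"`.
#' @param variables Columns to treat (default: all with any `NA`).
#' @param m Number of imputations (multiple imputation only).
#' @param cycles Chained-equation cycles per imputation.
#' @param seed RNG seed for the imputation draws.
#' @return A data.frame, or for multiple imputation a list of `m`
#'   data.frames of class `imputed_cohort`.
#' @export
impute_missing <- function(cohort,
                           method = c("complete_case", "single_mean_mode",
                                      "multiple_imputation"),
                           variables = NULL, m = 5, cycles = 5, seed = 1) {
  method <- match.arg(method)
  if (is.null(variables))
    variables <- names(cohort)[vapply(cohort, anyNA, TRUE)]
  fully_missing <- variables[vapply(variables, function(v)
    all(is.na(cohort[[v]])), TRUE)]
  if (length(fully_missing))
    stop("variable entirely missing: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  if (!length(variables)) {
    if (method == "multiple_imputation")
      return(structure(rep(list(cohort), m), class = "imputed_cohort"))
    return(cohort)
  }
  if (method == "complete_case") {
    keep <- stats::complete.cases(cohort[, variables, drop = FALSE])
    out <- cohort[keep, , drop = FALSE]
    attr(out, "n_dropped") <- sum(!keep)
    return(out)
  }
  if (method == "single_mean_mode") return(.fill_mean_mode(cohort, variables))
  imps <- lapply(seq_len(m), function(i)
    .mice_lite(cohort, variables, cycles = cycles,
               seed = seed * 1000L + i))
  structure(imps, class = "imputed_cohort")
}

.mode_of <- function(x) {
  tb <- table(x)
  names(tb)[which.max(tb)]
}

.is_continuous <- function(x) is.numeric(x) && length(unique(stats::na.omit(x))) > 8

.fill_mean_mode <- function(cohort, variables) {
  for (v in variables) {
    x <- cohort[[v]]
    na <- is.na(x)
    if (!any(na)) next
    if (.is_continuous(x)) {
      cohort[[v]][na] <- mean(x, na.rm = TRUE)
    } else {
      md <- .mode_of(x[!na])
      if (is.numeric(x)) md <- as.numeric(md)
      cohort[[v]][na] <- md
    }
  }
  cohort
}

# One chained-equations pass: regression imputation with stochastic draws.
.mice_lite <- function(cohort, variables, cycles, seed) {
  na_mask <- lapply(variables, function(v) is.na(cohort[[v]]))
  names(na_mask) <- variables
  filled <- .fill_mean_mode(cohort, variables)
  predictors <- variables
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  for (cycle in seq_len(cycles)) {
    for (v in variables) {
      miss <- na_mask[[v]]
      if (!any(miss)) next
      rhs <- setdiff(predictors, v)
      if (!length(rhs)) next
      dat <- filled[, c(v, rhs), drop = FALSE]
      x <- cohort[[v]]
      binary <- all(stats::na.omit(x) %in% c(0, 1))
      fml <- stats::reformulate(rhs, response = v)
      if (.is_continuous(x) && !binary) {
        fit <- stats::lm(fml, data = dat[!miss, , drop = FALSE])
        mu <- stats::predict(fit, newdata = dat[miss, , drop = FALSE])
        sig <- summary(fit)$sigma
        if (!is.finite(sig)) sig <- 0
        filled[[v]][miss] <- mu + stats::rnorm(sum(miss), 0, sig)
      } else if (binary) {
        fit <- suppressWarnings(
          stats::glm(fml, data = dat[!miss, , drop = FALSE],
                     family = stats::binomial()))
        p <- stats::predict(fit, newdata = dat[miss, , drop = FALSE],
                            type = "response")
        filled[[v]][miss] <- as.numeric(stats::runif(sum(miss)) < p)
      } else {
        obs <- cohort[[v]][!miss]
        filled[[v]][miss] <- sample(obs, sum(miss), replace = TRUE)
      }
    }
  }
  filled
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance `T = W + (1 + 1/m) B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance; df by the standard
#' Rubin formula.
#'
#' @param estimates Numeric vector (or matrix, terms in columns) of
#'   per-imputation estimates.
#' @param variances Matching squared standard errors.
#' @return Data.frame `estimate`, `within`, `between`, `total_var`, `se`,
#'   `df`.
#' @export
rubin_pool <- function(estimates, variances) {
  est <- as.matrix(estimates)
  varr <- as.matrix(variances)
  if (!all(dim(est) == dim(varr)))
    stop("estimates and variances must have matching shape", call. = FALSE)
  m <- nrow(est)
  if (m < 2) stop("need at least 2 imputations", call. = FALSE)
  qbar <- colMeans(est)
  w <- colMeans(varr)
  b <- apply(est, 2, stats::var)
  t_var <- w + (1 + 1 / m) * b
  r <- (1 + 1 / m) * b / w
  df <- (m - 1) * (1 + 1 / r)^2
  out <- data.frame(estimate = qbar, within = w, between = b,
                    total_var = t_var, se = sqrt(t_var), df = df)
  rownames(out) <- colnames(est)
  out
}
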