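# Descriptive and inferential group comparisons: the workhorse statistics
# of the validation pipeline (descriptives, ANOVA, Mann-Whitney, chi-square,
# Pearson correlation, Kolmogorov-Smirnov normality screen, per-component
# contrasts).

#' Describe variables by group
#'
#' Continuous variables are summarized as mean/sd per group, categorical
#' ones as count/percent per level; missing values are counted and excluded
#' from denominators. An `All` pseudo-group covering the whole cohort is
#' always included.
#'
#' @param cohort Data.frame.
#' @param grouping Factor/vector of group labels (length `nrow(cohort)`),
#'   or `NULL` for the overall column only.
#' @param variables Character vector of column names.
#' @param continuous Optional character vector forcing named variables to be
#'   summarized as continuous; by default numerics with more than 8 distinct
#'   values are continuous and everything else (including 0/1 flags) is
#'   categorical.
#' @return Tidy data.frame: `variable`, `group`, `level` (`NA` for
#'   continuous), `n`, `mean`, `sd`, `count`, `pct`, `n_missing`.
#' @export
describe_groups <- function(cohort, grouping = NULL, variables,
                            continuous = NULL) {
  absent <- setdiff(variables, names(cohort))
  if (length(absent))
    stop("variables not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (is.null(grouping)) grouping <- rep("All", nrow(cohort))
  grouping <- as.factor(grouping)
  if (any(table(grouping) == 0)) stop("empty group", call. = FALSE)
  groups <- unique(c("All", levels(grouping)))
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    # low-cardinality numerics (0/1 flags etc.) are categorical by default
    is_cont <- v %in% continuous ||
      (is.numeric(x) && length(unique(stats::na.omit(x))) > 8)
    for (g in groups) {
      sel <- if (g == "All") rep(TRUE, length(x)) else grouping == g
      xs <- x[sel]
      n_missing <- sum(is.na(xs))
      xs <- xs[!is.na(xs)]
      if (is_cont) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, group = g, level = NA_character_,
          n = length(xs), mean = mean(xs), sd = stats::sd(xs),
          count = NA_integer_, pct = NA_real_, n_missing = n_missing)
      } else {
        xs <- as.factor(xs)
        for (lev in levels(xs)) {
          cnt <- sum(xs == lev)
          rows[[length(rows) + 1L]] <- data.frame(
            variable = v, group = g, level = lev,
            n = length(xs), mean = NA_real_, sd = NA_real_,
            count = cnt, pct = 100 * cnt / length(xs),
            n_missing = n_missing)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a continuous variable across groups
#'
#' `test = "anova"` runs a one-way fixed-effects ANOVA (equal-variance F
#' test) over two or more groups; `test = "mann_whitney"` a two-sided
#' Mann-Whitney U over exactly two groups, exact for combined n <= 20
#' without ties, otherwise the tie-corrected normal approximation (no
#' continuity correction).
#'
#' @param cohort Data.frame.
#' @param grouping Group labels, length `nrow(cohort)`.
#' @param variable Column name.
#' @param test `"anova"` or `"mann_whitney"`.
#' @return List `statistic` (F or U), `p`, `test`, `df` (ANOVA only).
#' @export
compare_continuous <- function(cohort, grouping, variable,
                               test = c("anova", "mann_whitney")) {
  test <- match.arg(test)
  x <- cohort[[variable]]
  g <- as.factor(grouping)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (test == "anova") {
    if (nlevels(g) < 2) stop("ANOVA needs >= 2 groups", call. = FALSE)
    if (any(table(g) < 2)) stop("ANOVA needs >= 2 observations per group",
                                call. = FALSE)
    fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
    list(statistic = unname(fit$statistic), p = fit$p.value, test = "anova",
         df = unname(fit$parameter))
  } else {
    if (nlevels(g) != 2) stop("Mann-Whitney needs exactly 2 groups",
                              call. = FALSE)
    x1 <- x[g == levels(g)[1L]]
    x2 <- x[g == levels(g)[2L]]
    exact <- (length(x1) + length(x2)) <= 20 && !anyDuplicated(c(x1, x2))
    wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = exact,
                                              correct = FALSE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         test = "mann_whitney", df = NA_real_)
  }
}

#' Pearson chi-square test on a crosstab
#'
#' Pearson chi-square without continuity correction,
#' `df = (r - 1)(c - 1)`.
#'
#' @param cohort Data.frame (ignored when `variable` is a table).
#' @param grouping Group labels.
#' @param variable Column name, or a pre-built contingency `table`/matrix
#'   (then `cohort`/`grouping` are unused).
#' @return List `statistic`, `p`, `df`, `table`.
#' @export
compare_categorical <- function(cohort = NULL, grouping = NULL, variable) {
  if (is.table(variable) || is.matrix(variable)) {
    tab <- as.table(variable)
  } else {
    x <- cohort[[variable]]
    keep <- !is.na(x) & !is.na(grouping)
    tab <- table(droplevels(as.factor(grouping[keep])),
                 droplevels(as.factor(x[keep])))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), table = tab)
}

#' Pearson correlation between diet score and cognitive tests
#'
#' @param cohort Data.frame with a `diet_total` column (or supply `score`).
#' @param test_scores Character vector of test-score column names.
#' @param score Optional explicit score vector.
#' @return Data.frame `test`, `r`, `p`, `n`.
#' @export
correlate_score_cognition <- function(cohort, test_scores,
                                      score = cohort$diet_total) {
  rows <- lapply(test_scores, function(v) {
    y <- cohort[[v]]
    keep <- !is.na(score) & !is.na(y)
    xs <- score[keep]; ys <- y[keep]
    if (length(xs) < 3) stop("need >= 3 paired observations for ", v,
                             call. = FALSE)
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
      stop("constant input: correlation undefined for ", v, call. = FALSE)
    ct <- stats::cor.test(xs, ys, method = "pearson")
    data.frame(test = v, r = unname(ct$estimate), p = ct$p.value,
               n = length(xs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' KS statistic of the sample against a normal with the sample's own mean
#' and sd (no Lilliefors correction of the p-value; the p is therefore
#' conservative and used only as a screen).
#'
#' @param values Numeric vector, >= 5 non-missing observations.
#' @return List `statistic`, `p`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("need >= 5 observations", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant input", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                        stats::sd(values)))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Per-component score contrast between MCI and non-MCI
#'
#' Mean/sd of every component score (plus the total) by MCI status with a
#' Mann-Whitney p per row.
#'
#' @param cohort Data.frame with `score_<component>` columns, `diet_total`,
#'   and a logical/0-1 `mci` status column named by `status`.
#' @param status Column name of the MCI indicator (default `"true_mci"`).
#' @return Data.frame `component`, `mean_all`, `sd_all`, `mean_non_mci`,
#'   `sd_non_mci`, `mean_mci`, `sd_mci`, `p`.
#' @export
compare_components <- function(cohort, status = "true_mci") {
  comp_cols <- setdiff(grep("^score_", names(cohort), value = TRUE),
                       "score_group")
  if (!length(comp_cols)) stop("no score_<component> columns", call. = FALSE)
  if (!status %in% names(cohort)) stop("no status column ", status, call. = FALSE)
  mci <- as.logical(cohort[[status]])
  rows <- lapply(c(comp_cols, "diet_total"), function(v) {
    x <- cohort[[v]]
    mw <- compare_continuous(cohort, ifelse(mci, "MCI", "non-MCI"), v,
                             test = "mann_whitney")
    data.frame(component = sub("^score_", "", v),
               mean_all = mean(x, na.rm = TRUE), sd_all = stats::sd(x, na.rm = TRUE),
               mean_non_mci = mean(x[!mci], na.rm = TRUE),
               sd_non_mci = stats::sd(x[!mci], na.rm = TRUE),
               mean_mci = mean(x[mci], na.rm = TRUE),
               sd_mci = stats::sd(x[mci], na.rm = TRUE),
               p = mw$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
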