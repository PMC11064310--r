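# Banded dietary-index scoring: rule tables, unit normalization,
# component and profile scoring.

#' Days-per-month convention used for frequency normalization
#'
#' One month is taken as 30.44 days, i.e. 4.348 weeks, so an intake of
#' "1 serving/month" equals 1/4.348 = 0.23 servings/week.
#' @export
WEEKS_PER_MONTH <- 4.348

.valid_units <- c("per_day", "per_week", "per_month")

#' Construct a frequency value
#'
#' A frequency value pairs a non-negative amount (servings, glasses or
#' tablespoons) with the time unit it was ascertained in.
#'
#' @param amount Non-negative numeric amount.
#' @param unit One of `"per_day"`, `"per_week"`, `"per_month"`.
#' @return An object of class `frequency_value`.
#' @export
frequency_value <- function(amount, unit) {
  if (!is.numeric(amount) || length(amount) != 1L || is.na(amount) || amount < 0)
    stop("`amount` must be a single non-negative number", call. = FALSE)
  if (!is.character(unit) || length(unit) != 1L || !unit %in% .valid_units)
    stop("`unit` must be one of ", paste(.valid_units, collapse = ", "),
         call. = FALSE)
  structure(list(amount = as.numeric(amount), unit = unit),
            class = "frequency_value")
}

#' Normalize an intake frequency to servings per week
#'
#' The canonical unit of the scoring tables is servings/week: per-day
#' amounts are multiplied by 7, per-month amounts divided by 4.348
#' (30.44-day month).
#'
#' @param value A [frequency_value()], or a numeric amount when `unit` is
#'   given.
#' @param unit Optional unit string when `value` is a bare numeric.
#' @return Servings per week (numeric, vectorized over a numeric `value`).
#' @examples
#' normalize_frequency(frequency_value(1, "per_day"))   # 7
#' normalize_frequency(1, "per_month")                  # 0.23
#' @export
normalize_frequency <- function(value, unit = NULL) {
  if (inherits(value, "frequency_value")) {
    amount <- value$amount
    unit <- value$unit
  } else {
    amount <- value
    if (is.null(unit)) stop("`unit` is required for a bare amount", call. = FALSE)
  }
  if (!all(unit %in% .valid_units))
    stop("unknown unit: ", paste(setdiff(unique(unit), .valid_units), collapse = ", "),
         call. = FALSE)
  if (any(amount < 0, na.rm = TRUE)) stop("amount must be >= 0", call. = FALSE)
  factor <- c(per_day = 7, per_week = 1, per_month = 1 / WEEKS_PER_MONTH)[unit]
  unname(amount * factor)
}

# ---- rule-set loading and validation ---------------------------------------

.builtin_tables <- c(
  "MY-MINDD"      = "rules_mymindd.json",
  "MIND-original" = "rules_mind_original.json"
)
.builtin_component_counts <- c("MY-MINDD" = 11L, "MIND-original" = 15L)

#' Load and validate a scoring rule table
#'
#' Rule tables are JSON documents declaring, per component, a polarity
#' (healthy/unhealthy), an input kind (frequency or categorical), and either
#' an ordered list of half-open score bands partitioning `[0, Inf)` in
#' servings/week, or a category-to-points map. The two built-in tables
#' (`"MY-MINDD"`, `"MIND-original"`) ship with the package.
#'
#' @param table Either a built-in name (`"MY-MINDD"`, `"MIND-original"`) or a
#'   path to a JSON rule document.
#' @return A validated `scoring_rule_set`.
#' @export
load_scoring_table <- function(table = "MY-MINDD") {
  if (table %in% names(.builtin_tables)) {
    path <- system.file("extdata", .builtin_tables[[table]], package = "mymindd")
    if (!nzchar(path)) stop("packaged rule table not found: ", table, call. = FALSE)
  } else if (file.exists(table)) {
    path <- table
  } else {
    stop("unknown rule set: '", table,
         "' (not a built-in name and not an existing file)", call. = FALSE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- .validate_rule_set(doc)
  if (rules$name %in% names(.builtin_component_counts) &&
      length(rules$components) != .builtin_component_counts[[rules$name]])
    stop(rules$name, " must have ", .builtin_component_counts[[rules$name]],
         " components, found ", length(rules$components), call. = FALSE)
  rules
}

.validate_band <- function(b, comp_id) {
  up <- if (is.null(b$upper)) Inf else as.numeric(b$upper)
  lo <- as.numeric(b$lower)
  if (is.na(lo) || lo < 0 || lo > up)
    stop("component '", comp_id, "': malformed band [", lo, ", ", up, "]",
         call. = FALSE)
  if (!b$points %in% c(0, 0.5, 1))
    stop("component '", comp_id, "': band points must be 0, 0.5 or 1",
         call. = FALSE)
  list(lower = lo, upper = up,
       lower_closed = isTRUE(b$lower_closed),
       upper_closed = isTRUE(b$upper_closed),
       points = as.numeric(b$points))
}

# Bands must partition [0, Inf): start closed at 0, adjacent bands share a
# boundary with complementary closure, last band unbounded.
.check_partition <- function(bands, comp_id) {
  ord <- order(vapply(bands, `[[`, 0, "lower"),
               !vapply(bands, `[[`, TRUE, "lower_closed"))
  bands <- bands[ord]
  first <- bands[[1L]]
  if (first$lower != 0 || !first$lower_closed)
    stop("component '", comp_id, "': bands must start closed at 0", call. = FALSE)
  for (i in seq_along(bands)[-1L]) {
    prev <- bands[[i - 1L]]; cur <- bands[[i]]
    if (cur$lower != prev$upper || cur$lower_closed == prev$upper_closed)
      stop("component '", comp_id,
           "': bands overlap or leave a gap at ", format(cur$lower), call. = FALSE)
  }
  last <- bands[[length(bands)]]
  if (is.finite(last$upper))
    stop("component '", comp_id, "': bands must cover [0, Inf)", call. = FALSE)
  bands
}

.validate_component <- function(comp) {
  id <- comp$id
  if (is.null(id)) stop("component without id", call. = FALSE)
  if (!comp$polarity %in% c("healthy", "unhealthy"))
    stop("component '", id, "': polarity must be healthy/unhealthy", call. = FALSE)
  kind <- comp$input_kind
  if (!kind %in% c("frequency", "categorical"))
    stop("component '", id, "': input_kind must be frequency/categorical",
         call. = FALSE)
  out <- list(component_id = id,
              display_name = comp$display_name %||% id,
              polarity = comp$polarity,
              input_kind = kind,
              monotone = comp$monotone %||% TRUE)
  if (kind == "frequency") {
    bands <- lapply(comp$bands, .validate_band, comp_id = id)
    bands <- .check_partition(bands, id)
    pts <- vapply(bands, `[[`, 0, "points")
    if (isTRUE(out$monotone)) {
      diffs <- diff(pts)
      ok <- if (comp$polarity == "healthy") all(diffs >= 0) else all(diffs <= 0)
      if (!ok)
        stop("component '", id, "': band points violate ", comp$polarity,
             " monotonicity", call. = FALSE)
    }
    out$bands <- bands
  } else {
    cats <- unlist(comp$categories)
    if (is.null(cats) || is.null(names(cats)) ||
        !all(cats %in% c(0, 0.5, 1)))
      stop("component '", id, "': categorical map must assign 0/0.5/1",
           call. = FALSE)
    out$categories <- cats
  }
  structure(out, class = "component_rule")
}

.validate_rule_set <- function(doc) {
  if (is.null(doc$name)) stop("rule document lacks a name", call. = FALSE)
  comps <- lapply(doc$components, .validate_component)
  ids <- vapply(comps, `[[`, "", "component_id")
  if (anyDuplicated(ids))
    stop("duplicate component ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(comps) <- ids
  max_total <- sum(vapply(comps, function(cp) {
    if (cp$input_kind == "frequency") max(vapply(cp$bands, `[[`, 0, "points"))
    else max(cp$categories)
  }, 0))
  declared <- doc$max_total %||% max_total
  if (!isTRUE(all.equal(as.numeric(declared), max_total)))
    stop("declared max_total ", declared, " != sum of component maxima ",
         max_total, call. = FALSE)
  structure(list(name = doc$name, components = comps, max_total = max_total),
            class = "scoring_rule_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scoring_rule_set <- function(x, ...) {
  pol <- table(vapply(x$components, `[[`, "", "polarity"))
  cat("<scoring_rule_set> ", x$name, ": ", length(x$components),
      " components (", pol[["healthy"]], " healthy, ",
      pol[["unhealthy"]], " unhealthy), max total ", x$max_total, "\n", sep = "")
  invisible(x)
}

# ---- component / profile scoring -------------------------------------------

#' Score one component
#'
#' Looks up the unique score band containing the intake (after unit
#' normalization to servings/week) or the category's mapped points.
#' Missing intake (`NA` or `NULL`) yields `NA` rather than a silent 0.
#'
#' @param rule A `component_rule` from a [load_scoring_table()] rule set, or a
#'   rule set together with `component` to select one.
#' @param intake A [frequency_value()], a numeric servings/week amount, or a
#'   category string for categorical components.
#' @param component Component id when `rule` is a whole rule set.
#' @return Points in `{0, 0.5, 1}`, or `NA` for missing intake.
#' @export
score_component <- function(rule, intake, component = NULL) {
  if (inherits(rule, "scoring_rule_set")) {
    if (is.null(component)) stop("`component` needed with a rule set", call. = FALSE)
    if (!component %in% names(rule$components))
      stop("unknown component: ", component, call. = FALSE)
    rule <- rule$components[[component]]
  }
  if (is.null(intake) || (length(intake) == 1L && !is.list(intake) && is.na(intake)))
    return(NA_real_)
  if (rule$input_kind == "categorical") {
    if (inherits(intake, "frequency_value") || is.numeric(intake))
      stop("component '", rule$component_id, "' takes a category, not a frequency",
           call. = FALSE)
    if (!intake %in% names(rule$categories))
      stop("component '", rule$component_id, "': unknown category '", intake, "'",
           call. = FALSE)
    return(unname(rule$categories[[intake]]))
  }
  if (inherits(intake, "frequency_value")) {
    x <- normalize_frequency(intake)
  } else if (is.numeric(intake)) {
    x <- as.numeric(intake)
  } else {
    stop("component '", rule$component_id, "' takes a frequency", call. = FALSE)
  }
  score_band_lookup(rule, x)
}

#' Vectorized band lookup on normalized servings/week
#'
#' @param rule A frequency-kind `component_rule`.
#' @param x Numeric vector of servings/week; `NA` propagates.
#' @return Numeric vector of points.
#' @export
score_band_lookup <- function(rule, x) {
  if (rule$input_kind != "frequency")
    stop("band lookup needs a frequency component", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("intake must be >= 0", call. = FALSE)
  out <- rep(NA_real_, length(x))
  for (b in rule$bands) {
    lo_ok <- if (b$lower_closed) x >= b$lower else x > b$lower
    hi_ok <- if (b$upper_closed) x <= b$upper else x < b$upper
    sel <- which(lo_ok & hi_ok)
    out[sel] <- b$points
  }
  out
}

#' Construct an intake profile
#'
#' @param participant_id Identifier.
#' @param frequencies Named list of [frequency_value()]s (or servings/week
#'   numerics), keyed by component id; `NA` marks explicit missing.
#' @param categories Named character vector/list of categorical intakes
#'   (e.g. `olive_oil = "primary"`).
#' @return An `intake_profile`.
#' @export
intake_profile <- function(participant_id, frequencies = list(), categories = list()) {
  structure(list(participant_id = participant_id,
                 frequencies = frequencies,
                 categories = as.list(categories)),
            class = "intake_profile")
}

#' Score a full intake profile against a rule set
#'
#' Sums component points to the diet-index total. Components with missing
#' intake are listed in `missing_components`; under the default
#' `missing = "refuse"` policy the total is `NA` and the result flagged
#' incomplete, under `missing = "zero"` missing components contribute 0.
#'
#' @param rules A `scoring_rule_set`.
#' @param profile An [intake_profile()].
#' @param missing Missing-component policy, `"refuse"` or `"zero"`.
#' @return A `diet_score_result` with `component_scores`, `total`,
#'   `missing_components` and `incomplete`.
#' @export
score_profile <- function(rules, profile, missing = c("refuse", "zero")) {
  missing <- match.arg(missing)
  if (!inherits(rules, "scoring_rule_set")) stop("`rules` must be a scoring_rule_set",
                                                 call. = FALSE)
  if (!inherits(profile, "intake_profile")) stop("`profile` must be an intake_profile",
                                                 call. = FALSE)
  if (length(profile$frequencies) + length(profile$categories) == 0L)
    stop("empty intake profile", call. = FALSE)
  scores <- vapply(rules$components, function(cp) {
    id <- cp$component_id
    intake <- if (cp$input_kind == "frequency") profile$frequencies[[id]]
              else profile$categories[[id]]
    score_component(cp, intake)
  }, 0)
  miss <- names(scores)[is.na(scores)]
  if (missing == "zero") {
    total <- sum(scores, na.rm = TRUE)
    incomplete <- FALSE
  } else {
    total <- if (length(miss)) NA_real_ else sum(scores)
    incomplete <- length(miss) > 0L
  }
  structure(list(participant_id = profile$participant_id,
                 component_scores = scores,
                 total = total,
                 missing_components = miss,
                 incomplete = incomplete),
            class = "diet_score_result")
}

#' @export
print.diet_score_result <- function(x, ...) {
  cat("<diet_score_result> participant ", x$participant_id, ": total ",
      if (is.na(x$total)) "NA (incomplete)" else x$total, "\n", sep = "")
  invisible(x)
}

#' Score a cohort table of intakes
#'
#' Expects the cohort CSV layout: per frequency component either a pair of
#' columns `<id>_amount` / `<id>_unit` or a single `<id>_wk` column already
#' in servings/week; categorical components use `<id>` columns (e.g.
#' `olive_oil` with values `primary` / `not_primary`).
#'
#' @param cohort A data.frame, one row per participant, with an `id` column.
#' @param rules A `scoring_rule_set` (default the packaged MY-MINDD table).
#' @param missing Missing-component policy, see [score_profile()].
#' @return A data.frame `id`, `score_<component>` columns, `diet_total`,
#'   `diet_incomplete`, in a stable column order.
#' @export
score_cohort <- function(cohort, rules = load_scoring_table("MY-MINDD"),
                         missing = c("refuse", "zero")) {
  missing <- match.arg(missing)
  if (!"id" %in% names(cohort)) stop("cohort must have an `id` column", call. = FALSE)
  n <- nrow(cohort)
  comp_scores <- lapply(rules$components, function(cp) {
    id <- cp$component_id
    if (cp$input_kind == "categorical") {
      if (!id %in% names(cohort)) return(rep(NA_real_, n))
      vals <- as.character(cohort[[id]])
      out <- rep(NA_real_, n)
      known <- !is.na(vals)
      bad <- known & !vals %in% names(cp$categories)
      if (any(bad))
        stop("component '", id, "': unknown categories: ",
             paste(unique(vals[bad]), collapse = ", "), call. = FALSE)
      out[known] <- unname(cp$categories[vals[known]])
      return(out)
    }
    wk_col <- paste0(id, "_wk")
    amt_col <- paste0(id, "_amount"); unit_col <- paste0(id, "_unit")
    if (wk_col %in% names(cohort)) {
      x <- as.numeric(cohort[[wk_col]])
    } else if (all(c(amt_col, unit_col) %in% names(cohort))) {
      amt <- as.numeric(cohort[[amt_col]])
      unit <- as.character(cohort[[unit_col]])
      x <- rep(NA_real_, n)
      ok <- !is.na(amt) & !is.na(unit)
      x[ok] <- normalize_frequency(amt[ok], unit[ok])
    } else {
      return(rep(NA_real_, n))
    }
    out <- rep(NA_real_, n)
    ok <- !is.na(x)
    out[ok] <- score_band_lookup(cp, x[ok])
    out
  })
  names(comp_scores) <- paste0("score_", names(rules$components))
  sc <- as.data.frame(comp_scores)
  mat <- as.matrix(sc)
  n_miss <- rowSums(is.na(mat))
  if (missing == "zero") {
    total <- rowSums(mat, na.rm = TRUE)
    incomplete <- rep(FALSE, n)
  } else {
    total <- ifelse(n_miss > 0, NA_real_, rowSums(mat))
    incomplete <- n_miss > 0
  }
  cbind(data.frame(id = cohort$id), sc,
        data.frame(diet_total = total, diet_incomplete = incomplete))
}
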