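# MCI operationalization: RAVLT z-score criterion, Petersen-style
# classification, and derived covariate categories.

#' MCI classification criteria configuration
#'
#' @param ravlt_z_threshold Memory-impairment threshold on the RAVLT z scale;
#'   must be negative (default -1.5, i.e. 1.5 SD below the reference mean).
#' @param ravlt_reference `"cohort"` (reference mean/SD estimated once from
#'   the non-dementia sample) or a `c(mean =, sd =)` pair of external norms.
#' @param iadl_intact_cutoff Minimum IADL score counted as "no limitation";
#'   `NA` means use the maximum observed in the cohort.
#' @param global_function_mmse_cutoff Minimum MMSE counted as preserved
#'   global function (default 19).
#' @return An `mci_criteria` list.
#' @export
mci_criteria <- function(ravlt_z_threshold = -1.5,
                         ravlt_reference = "cohort",
                         iadl_intact_cutoff = NA_real_,
                         global_function_mmse_cutoff = 19) {
  if (!is.numeric(ravlt_z_threshold) || ravlt_z_threshold >= 0)
    stop("`ravlt_z_threshold` must be negative", call. = FALSE)
  structure(list(ravlt_z_threshold = ravlt_z_threshold,
                 ravlt_reference = ravlt_reference,
                 iadl_intact_cutoff = iadl_intact_cutoff,
                 global_function_mmse_cutoff = global_function_mmse_cutoff),
            class = "mci_criteria")
}

#' RAVLT z-score against a reference population
#'
#' @param score Observed RAVLT score(s).
#' @param ref_mean,ref_sd Reference mean and standard deviation; `ref_sd`
#'   must be positive.
#' @return `(score - ref_mean) / ref_sd`.
#' @export
ravlt_zscore <- function(score, ref_mean, ref_sd) {
  if (!is.numeric(ref_sd) || length(ref_sd) != 1L || is.na(ref_sd) || ref_sd <= 0)
    stop("`ref_sd` must be a single positive number", call. = FALSE)
  (score - ref_mean) / ref_sd
}

#' Classify mild cognitive impairment
#'
#' A participant is MCI iff all of: objective memory impairment (RAVLT
#' z-score at or below the threshold), intact instrumental activities of
#' daily living, subjective memory complaint, preserved global function
#' (MMSE at or above the cutoff), and no dementia. Participants with a
#' dementia diagnosis are returned as `"excluded-dementia"`.
#'
#' Vectorized: pass equal-length vectors to classify a cohort.
#'
#' @param ravlt,mmse,iadl Numeric test scores.
#' @param memory_complaint,dementia Logical flags.
#' @param cfg An [mci_criteria()] configuration.
#' @param reference `c(mean =, sd =)` RAVLT reference statistics.
#' @return Factor with levels `non-MCI`, `MCI`, `excluded-dementia`.
#' @export
classify_mci <- function(ravlt, mmse, iadl, memory_complaint, dementia,
                         cfg = mci_criteria(), reference) {
  fields <- list(ravlt = ravlt, mmse = mmse, iadl = iadl,
                 memory_complaint = memory_complaint, dementia = dementia)
  for (nm in names(fields))
    if (anyNA(fields[[nm]]))
      stop("missing required field: ", nm, call. = FALSE)
  if (length(reference) < 2L || is.na(reference[["sd"]]) || reference[["sd"]] <= 0)
    stop("`reference` must supply a positive sd", call. = FALSE)
  iadl_cut <- cfg$iadl_intact_cutoff
  if (is.na(iadl_cut)) iadl_cut <- max(iadl)
  z <- ravlt_zscore(ravlt, reference[["mean"]], reference[["sd"]])
  mci <- z <= cfg$ravlt_z_threshold &
    iadl >= iadl_cut &
    memory_complaint &
    mmse >= cfg$global_function_mmse_cutoff &
    !dementia
  out <- ifelse(dementia, "excluded-dementia", ifelse(mci, "MCI", "non-MCI"))
  factor(out, levels = c("non-MCI", "MCI", "excluded-dementia"))
}

#' Classify a cohort table, appending a status column
#'
#' Computes the RAVLT reference once from the non-dementia rows (unless
#' external norms are configured), then applies [classify_mci()] row-wise.
#' The reference is fixed: it is not re-estimated from the classified subset.
#'
#' @param cohort Data.frame with columns `ravlt`, `mmse`, `iadl`,
#'   `memory_complaint`, `dementia`.
#' @param cfg An [mci_criteria()].
#' @return The cohort with a `classified_mci` factor column appended; the
#'   reference used is attached as attribute `ravlt_reference`.
#' @export
classify_cohort <- function(cohort, cfg = mci_criteria()) {
  need <- c("ravlt", "mmse", "iadl", "memory_complaint", "dementia")
  absent <- setdiff(need, names(cohort))
  if (length(absent))
    stop("cohort lacks columns: ", paste(absent, collapse = ", "), call. = FALSE)
  if (identical(cfg$ravlt_reference, "cohort")) {
    ref_rows <- !cohort$dementia & !is.na(cohort$ravlt)
    reference <- c(mean = mean(cohort$ravlt[ref_rows]),
                   sd = stats::sd(cohort$ravlt[ref_rows]))
  } else {
    reference <- cfg$ravlt_reference
  }
  cohort$classified_mci <- classify_mci(
    cohort$ravlt, cohort$mmse, cohort$iadl,
    cohort$memory_complaint, cohort$dementia,
    cfg = cfg, reference = reference)
  attr(cohort, "ravlt_reference") <- reference
  cohort
}

#' BMI category
#'
#' WHO-style classes with half-open boundaries: underweight `< 18.5`, normal
#' `[18.5, 25)`, overweight `[25, 30)`, obese `>= 30` kg/m^2.
#'
#' @param bmi Positive numeric vector, kg/m^2.
#' @return Factor with the four ordered categories.
#' @export
bmi_category <- function(bmi) {
  if (any(is.na(bmi)) || any(bmi <= 0))
    stop("`bmi` must be positive", call. = FALSE)
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Depressive-symptom dichotomy from GDS-15
#'
#' @param gds15 Integer scores 0-15.
#' @param cutoff Scores at or above `cutoff` count as depressive symptoms
#'   (default 5, the standard GDS-15 screen).
#' @return Logical vector.
#' @export
depressive_symptoms <- function(gds15, cutoff = 5) {
  if (any(gds15 < 0 | gds15 > 15, na.rm = TRUE))
    stop("`gds15` must lie in [0, 15]", call. = FALSE)
  gds15 >= cutoff
}
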