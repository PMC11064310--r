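# Quantile score-group assignment ("tertiles" in the source nomenclature,
# four groups by default).

#' Assign quantile score groups
#'
#' Cuts scores into `k` groups at the `1/k ... (k-1)/k` empirical quantiles
#' (type 7). Ties at a boundary go to the lower group, so group sizes can be
#' unequal but are deterministic. Labels are `T1 < T2 < ... < Tk` ordered
#' by score.
#'
#' @param scores Numeric vector (no `NA`).
#' @param k Number of groups (default 4).
#' @return List with `group` (factor, length of `scores`), `boundaries`
#'   (the `k - 1` cut values) and `k`.
#' @export
assign_score_groups <- function(scores, k = 4) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (anyNA(scores)) stop("`scores` must not contain NA", call. = FALSE)
  if (length(unique(scores)) < k)
    stop("need at least ", k, " distinct score values", call. = FALSE)
  boundaries <- stats::quantile(scores, probs = seq_len(k - 1) / k,
                                type = 7, names = FALSE)
  idx <- 1L + vapply(scores, function(s) sum(s > boundaries), 0L)
  labels <- paste0("T", seq_len(k))
  list(group = factor(labels[idx], levels = labels),
       boundaries = boundaries, k = as.integer(k))
}
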