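# Small distribution utilities for the synthetic-cohort generator:
# inverse-CDF truncated normals, moment matching, and calibration solvers.

#' Truncated-normal inverse CDF
#'
#' Maps a uniform to a draw from N(mu, sd) truncated to `[lower, upper]`.
#'
#' @param u Uniform(0,1) values.
#' @param mu,sd Location and scale of the untruncated normal.
#' @param lower,upper Truncation bounds (may be infinite).
#' @return Numeric vector.
#' @export
qtruncnorm <- function(u, mu, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(min(max(mu, lower), upper), length(u)))
  pa <- stats::pnorm(lower, mu, sd)
  pb <- stats::pnorm(upper, mu, sd)
  stats::qnorm(pa + u * (pb - pa), mu, sd)
}

# Mean of N(mu, sd) truncated to [a, b]. When mu sits far outside the
# bounds the mass underflows; the mean then collapses to the nearer bound.
.truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  m <- mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / z
  if (!is.finite(m) || z < 1e-12) m <- if (al > 0) a else b
  m
}

#' Solve the location of a truncated normal for a target mean
#'
#' Finds `mu` such that N(mu, sd) truncated to `[lower, upper]` has mean
#' `target`. Used so published (untruncated) moments are reproduced despite
#' instrument bounds.
#'
#' @param target Desired truncated mean.
#' @param sd Scale of the untruncated normal (> 0).
#' @param lower,upper Truncation bounds.
#' @return The solved `mu`.
#' @export
truncnorm_mu_for_mean <- function(target, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (is.infinite(lower) && is.infinite(upper)) return(target)
  if (target <= lower || target >= upper)
    stop("target mean must lie strictly inside the truncation bounds",
         call. = FALSE)
  f <- function(mu) .truncnorm_mean(mu, sd, lower, upper) - target
  stats::uniroot(f, lower = target - 12 * sd, upper = target + 12 * sd,
                 tol = 1e-10)$root
}

#' Log-normal parameters by moment matching
#'
#' @param mean,sd Target arithmetic mean and standard deviation (> 0).
#' @return `c(meanlog =, sdlog =)`.
#' @export
lnorm_moment_match <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("mean and sd must be > 0", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Expected component score of a gamma(shape, scale) intake under a banded
# frequency rule (continuous distribution: open/closed bounds immaterial).
.expected_band_score <- function(rule, shape, scale) {
  sum(vapply(rule$bands, function(b) {
    p <- stats::pgamma(b$upper, shape = shape, scale = scale) -
      stats::pgamma(b$lower, shape = shape, scale = scale)
    b$points * p
  }, 0))
}

#' Calibrate gamma intake scales to target component-score means
#'
#' For each frequency component, solves the gamma scale (shape fixed) so the
#' expected 0/0.5/1 component score equals the target mean. The expected
#' score is monotone in the scale (stochastic ordering), so the root is
#' unique.
#'
#' @param rules A `scoring_rule_set`.
#' @param targets Named numeric vector of target score means in (0, 1),
#'   keyed by component id.
#' @param shape Gamma shape shared by all components (default 1.5,
#'   right-skewed as food-frequency data are).
#' @return Data.frame `component`, `shape`, `scale`, `target`.
#' @export
calibrate_intake_model <- function(rules, targets, shape = 1.5) {
  ids <- names(rules$components)
  freq_ids <- ids[vapply(rules$components, function(cp)
    cp$input_kind == "frequency", TRUE)]
  absent <- setdiff(freq_ids, names(targets))
  if (length(absent))
    stop("no score target for: ", paste(absent, collapse = ", "), call. = FALSE)
  rows <- lapply(freq_ids, function(id) {
    tgt <- targets[[id]]
    if (tgt <= 0 || tgt >= 1)
      stop("target for '", id, "' must be in (0,1)", call. = FALSE)
    f <- function(ls) .expected_band_score(rules$components[[id]],
                                           shape, exp(ls)) - tgt
    ls <- stats::uniroot(f, lower = -14, upper = 14, tol = 1e-10)$root
    data.frame(component = id, shape = shape, scale = exp(ls), target = tgt)
  })
  do.call(rbind, rows)
}

#' Solve a binomial success probability for a tail target
#'
#' Finds `p` with `P(Binomial(size, p) >= cutoff) = target`; used to pick the
#' GDS-15 item probability matching a depressive-symptom prevalence.
#'
#' @param target Tail probability in (0, 1).
#' @param size Number of trials.
#' @param cutoff Tail threshold (at or above).
#' @return Success probability `p`.
#' @export
binom_tail_solve <- function(target, size = 15, cutoff = 5) {
  if (target <= 0 || target >= 1) stop("target must be in (0,1)", call. = FALSE)
  f <- function(p) (1 - stats::pbinom(cutoff - 1, size, p)) - target
  stats::uniroot(f, lower = 1e-9, upper = 1 - 1e-9, tol = 1e-12)$root
}
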