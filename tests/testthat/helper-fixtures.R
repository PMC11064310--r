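# Shared fixtures: profiles at band extremes, a brute-force band-scan
# oracle, and a tiny hand-built cohort.

# Servings/week landing in the best / middle / worst band of a component.
band_representative <- function(rule, which = c("best", "middle", "worst")) {
  which <- match.arg(which)
  pts <- vapply(rule$bands, `[[`, 0, "points")
  target <- switch(which, best = max(pts), worst = min(pts), middle = 0.5)
  b <- rule$bands[[which(pts == target)[1L]]]
  if (is.finite(b$upper)) {
    mid <- (b$lower + b$upper) / 2
    if (mid > b$lower || b$lower_closed) mid else b$upper
  } else if (b$lower_closed) b$lower else b$lower + 1
}

# Profile with every component in the requested band.
profile_at <- function(rules, which = "best", id = "p1") {
  freqs <- list(); cats <- list()
  for (cp in rules$components) {
    if (cp$input_kind == "categorical") {
      pts <- cp$categories
      target <- switch(which, best = max(pts), worst = min(pts), middle = 0.5)
      hit <- names(pts)[which(pts == target)[1L]]
      if (is.na(hit)) hit <- names(pts)[1L]
      cats[[cp$component_id]] <- hit
    } else {
      freqs[[cp$component_id]] <- band_representative(cp, which)
    }
  }
  intake_profile(id, frequencies = freqs, categories = cats)
}

# Independent oracle: linear scan of the band list, no vectorization tricks.
brute_force_score <- function(rule, x) {
  for (b in rule$bands) {
    lo <- if (b$lower_closed) x >= b$lower else x > b$lower
    hi <- if (b$upper_closed) x <= b$upper else x < b$upper
    if (lo && hi) return(b$points)
  }
  NA_real_
}

# Minimal complete cohort for classification / analysis unit tests.
tiny_cohort <- function(n = 12) {
  set.seed(99)
  data.frame(
    id = seq_len(n),
    ravlt = c(rep(1, n %/% 2), rep(8, n - n %/% 2)),
    mmse = rep(26, n),
    iadl = rep(14, n),
    memory_complaint = rep(TRUE, n),
    dementia = rep(FALSE, n)
  )
}
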