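# Shared fixtures, built in code.

# Small cohort for fast structural tests.
small_cohort <- function(n = 60, seed = 42, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

# Brute-force cutoff search, independent of optimize_cutoff(): direct
# recounts and survdiff calls per candidate, explicit max/tie-break loop.
brute_force_cutoff <- function(cohort, scores,
                               constraints = search_constraints()) {
  best <- NULL
  for (cc in sort(unique(scores))) {
    pos <- scores >= cc
    np <- sum(pos)
    n <- length(pos)
    if (np == 0 || np == n) next
    prev <- np / n
    if (prev < constraints$prevalence_min ||
        prev > constraints$prevalence_max) next
    p_surv <- vapply(c("os", "pfs"), function(ep) {
      tm <- cohort[[paste0(ep, "_time")]]
      ev <- cohort[[paste0(ep, "_event")]]
      if (sum(ev) == 0) return(NA_real_)
      sd <- survival::survdiff(survival::Surv(tm, ev) ~ pos)
      stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
    }, numeric(1))
    if (any(is.na(p_surv)) || any(p_surv > c(constraints$max_p_os,
                                             constraints$max_p_pfs))) next
    ppv <- sum(cohort$response[pos]) / np
    if (is.null(best) ||
        ppv > best$ppv + 1e-12 ||
        (abs(ppv - best$ppv) <= 1e-12 && p_surv[1] < best$p_os - 1e-12) ||
        (abs(ppv - best$ppv) <= 1e-12 &&
           abs(p_surv[1] - best$p_os) <= 1e-12 && cc < best$cutoff)) {
      best <- list(cutoff = cc, ppv = ppv, p_os = p_surv[[1]],
                   p_pfs = p_surv[[2]], prevalence = prev)
    }
  }
  best
}
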