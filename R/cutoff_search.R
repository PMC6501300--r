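#' Constraints for the PPV-maximizing cutoff search
#'
#' The search accepts a cutoff only if both the OS and the PFS two-group
#' log-rank p-values are at or below `max_p_os` / `max_p_pfs` and the
#' prevalence of score-positive patients falls in
#' `[prevalence_min, prevalence_max]`.
#'
#' @param max_p_os,max_p_pfs log-rank p-value caps (default 0.05 each).
#' @param prevalence_min,prevalence_max admissible positive-prevalence
#'   band (defaults 0.30 and 0.70).
#' @param confidence confidence level for the exact binomial PPV interval.
#' @return a list of class `search_constraints`.
#' @export
search_constraints <- function(max_p_os = 0.05, max_p_pfs = 0.05,
                               prevalence_min = 0.30, prevalence_max = 0.70,
                               confidence = 0.95) {
  check_scalar_num(max_p_os, "max_p_os", lower = 1e-12, upper = 1)
  check_scalar_num(max_p_pfs, "max_p_pfs", lower = 1e-12, upper = 1)
  check_scalar_num(prevalence_min, "prevalence_min", lower = 0, upper = 1)
  check_scalar_num(prevalence_max, "prevalence_max", lower = 0, upper = 1)
  check_that(prevalence_min < prevalence_max,
             "'prevalence_min' must be < 'prevalence_max'")
  check_scalar_num(confidence, "confidence", lower = 0.5, upper = 0.9999)
  structure(list(max_p_os = max_p_os, max_p_pfs = max_p_pfs,
                 prevalence_min = prevalence_min,
                 prevalence_max = prevalence_max,
                 confidence = confidence),
            class = "search_constraints")
}

#' PPV with exact binomial confidence interval
#'
#' PPV = responders among score-positive patients / all score-positive
#' patients (the objective response rate within the positive subgroup).
#' The interval is Clopper-Pearson (exact binomial), computed from the
#' beta quantile form.
#'
#' @param n_positive number of score-positive patients.
#' @param n_responders responders among them.
#' @param confidence confidence level (default 0.95).
#' @return a list: `ppv`, `lo`, `hi` (`ppv` is NA when `n_positive` = 0).
#' @export
ppv_with_ci <- function(n_positive, n_responders, confidence = 0.95) {
  check_that(n_positive >= 0 && n_responders >= 0,
             "counts must be non-negative")
  check_that(n_responders <= n_positive,
             "'n_responders' cannot exceed 'n_positive'")
  if (n_positive == 0) return(list(ppv = NA_real_, lo = NA_real_, hi = NA_real_))
  a <- 1 - confidence
  k <- n_responders; n <- n_positive
  lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  list(ppv = k / n, lo = lo, hi = hi)
}

#' Candidate cutoffs from observed scores
#'
#' The sorted unique observed score values. PPV, prevalence and the
#' log-rank statistics only change when the cutoff crosses an observed
#' value, so this grid is exhaustive for the ">= cutoff is positive" rule.
#'
#' @param scores numeric score vector (>= 2 values).
#' @return sorted unique candidates.
#' @export
candidate_cutoffs <- function(scores) {
  check_that(is.numeric(scores) && length(scores) >= 2 &&
               all(is.finite(scores)),
             "'scores' must be >= 2 finite numbers")
  sort(unique(scores))
}

#' Evaluate one cutoff on a cohort
#'
#' Dichotomizes scores at the cutoff (>= is positive), then computes
#' positive prevalence, PPV with its exact CI, and the two-group log-rank
#' p-values for OS and PFS. The cutoff is feasible when prevalence lies in
#' the constraint band and both p-values are at or below their caps; if
#' either group is empty the log-rank tests are undefined and the cutoff
#' is infeasible with the reason recorded.
#'
#' @param cohort data.frame with `response`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`.
#' @param scores score vector aligned to the cohort rows.
#' @param cutoff candidate cutoff.
#' @param constraints a [search_constraints()].
#' @return a one-row data.frame: `cutoff`, `prevalence`, `n_positive`,
#'   `n_responders_positive`, `ppv`, `ppv_lo`, `ppv_hi`, `p_os`, `p_pfs`,
#'   `feasible`, `reason`.
#' @export
evaluate_cutoff <- function(cohort, scores, cutoff,
                            constraints = search_constraints()) {
  check_that(length(scores) == nrow(cohort),
             "'scores' must align with the cohort rows")
  pos <- scores >= cutoff
  n <- length(pos)
  n_pos <- sum(pos)
  n_resp_pos <- sum(cohort$response[pos])
  prevalence <- n_pos / n
  ci <- ppv_with_ci(n_pos, n_resp_pos, constraints$confidence)

  p_os <- NA_real_; p_pfs <- NA_real_
  reason <- ""
  if (n_pos == 0 || n_pos == n) {
    reason <- "degenerate split: one group is empty"
  } else {
    p_os <- tryCatch(
      logrank(cohort$os_time[pos], cohort$os_event[pos],
              cohort$os_time[!pos], cohort$os_event[!pos])$p_value,
      error = function(e) NA_real_)
    p_pfs <- tryCatch(
      logrank(cohort$pfs_time[pos], cohort$pfs_event[pos],
              cohort$pfs_time[!pos], cohort$pfs_event[!pos])$p_value,
      error = function(e) NA_real_)
    if (is.na(p_os) || is.na(p_pfs)) reason <- "log-rank undefined (no events)"
  }
  feasible <- !is.na(p_os) && !is.na(p_pfs) &&
    p_os <= constraints$max_p_os && p_pfs <= constraints$max_p_pfs &&
    prevalence >= constraints$prevalence_min &&
    prevalence <= constraints$prevalence_max
  if (!feasible && reason == "") reason <- "constraints not met"
  data.frame(cutoff = cutoff, prevalence = prevalence,
             n_positive = n_pos, n_responders_positive = n_resp_pos,
             ppv = ci$ppv, ppv_lo = ci$lo, ppv_hi = ci$hi,
             p_os = p_os, p_pfs = p_pfs,
             feasible = feasible,
             reason = if (feasible) "" else reason,
             stringsAsFactors = FALSE)
}

#' PPV-maximizing cutoff under survival and prevalence constraints
#'
#' Evaluates every candidate cutoff (the observed unique scores) and picks
#' the feasible one with maximal PPV; ties are broken by smaller OS
#' log-rank p-value, then by smaller cutoff. When no candidate is
#' feasible, `best` is NULL and the full evaluation table is still
#' returned.
#'
#' @inheritParams evaluate_cutoff
#' @return a list of class `cutoff_search_result`: `best` (one-row
#'   data.frame or NULL), `all_evaluations` (data.frame over all
#'   candidates), `n_candidates`.
#' @export
optimize_cutoff <- function(cohort, scores,
                            constraints = search_constraints()) {
  cands <- candidate_cutoffs(scores)
  evals <- do.call(rbind, lapply(cands, function(cc)
    evaluate_cutoff(cohort, scores, cc, constraints)))
  feas <- evals[evals$feasible & !is.na(evals$ppv), , drop = FALSE]
  best <- NULL
  if (nrow(feas) > 0) {
    ord <- order(-feas$ppv, feas$p_os, feas$cutoff)
    best <- feas[ord[1], , drop = FALSE]
    rownames(best) <- NULL
  }
  structure(list(best = best, all_evaluations = evals,
                 n_candidates = length(cands)),
            class = "cutoff_search_result")
}
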