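#' Positive prevalence of a reference cohort
#'
#' Fraction of "positive" labels, carried at full precision (rounding is
#' for display only).
#'
#' @param labels character vector of "positive"/"negative" labels.
#' @return the positive fraction.
#' @export
reference_prevalence <- function(labels) {
  check_that(length(labels) > 0, "'labels' must be non-empty")
  check_that(all(labels %in% c("positive", "negative")),
             "'labels' must be \"positive\"/\"negative\"")
  mean(labels == "positive")
}

#' Transfer signature positivity by prevalence matching
#'
#' Ranks the target cohort by score and labels the top `q` fraction
#' positive: `n_positive = round(q * n)` (floor/ceiling available), and the
#' derived cutoff is the smallest positive score. Ties at the boundary are
#' resolved by stable input order with a warning, so exactly `n_positive`
#' patients are labeled positive even when scores tie.
#'
#' @param target_scores numeric score vector of the target cohort.
#' @param q positive prevalence to match, in \[0, 1\].
#' @param rounding how to turn `q * n` into a count: "round" (default),
#'   "floor" or "ceiling".
#' @return a list of class `transfer_result`: `matched_prevalence`
#'   (the achieved n_positive/n), `n_positive`, `derived_cutoff`
#'   (Inf when no patient is positive), `labels`.
#' @export
match_prevalence <- function(target_scores, q,
                             rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  check_that(is.numeric(target_scores) && length(target_scores) > 0 &&
               all(is.finite(target_scores)),
             "'target_scores' must be non-empty finite numbers")
  check_scalar_num(q, "q", lower = 0, upper = 1)
  n <- length(target_scores)
  n_pos <- switch(rounding,
                  round = round(q * n),
                  floor = floor(q * n),
                  ceiling = ceiling(q * n))
  n_pos <- as.integer(min(max(n_pos, 0L), n))
  labels <- rep("negative", n)
  cutoff <- Inf
  if (n_pos > 0) {
    ord <- order(target_scores, decreasing = TRUE)  # stable for ties
    top <- ord[seq_len(n_pos)]
    labels[top] <- "positive"
    cutoff <- min(target_scores[top])
    if (n_pos < n && any(target_scores[ord[-seq_len(n_pos)]] == cutoff)) {
      warning("score ties at the prevalence boundary; resolved by input order",
              call. = FALSE)
    }
  }
  structure(list(matched_prevalence = n_pos / n,
                 n_positive = n_pos,
                 derived_cutoff = cutoff,
                 labels = labels),
            class = "transfer_result")
}
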