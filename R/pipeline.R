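#' Stratified train/test split balanced on clinical variables
#'
#' Partitions a cohort into train and test sets that are balanced on the
#' joint strata of the given variables: within each stratum, patients are
#' allocated proportionally with largest-remainder rounding so that the
#' train set has exactly `round(train_fraction * n)` patients overall.
#' Numeric balance variables with many distinct values (e.g. age, prior
#' therapy lines) are binned into tertiles for stratification only; they
#' stay continuous in the data. Strata of size 1 are allocated by the same
#' largest-remainder rule, which amounts to a seeded coin weighted by the
#' stratum quota remainder.
#'
#' @param cohort cohort data.frame.
#' @param train_fraction fraction of patients for the training set.
#' @param balance_variables column names to balance on. The default
#'   mirrors the trial split: manual PD-L1 status (>= 25%), objective
#'   response, prior therapy lines, tumor stage and gender.
#' @param seed integer seed for within-stratum shuffling.
#' @param n_bins number of quantile bins for numeric balance variables.
#' @return a list with `train` and `test` data.frames (a partition of the
#'   cohort rows).
#' @export
stratified_split <- function(cohort, train_fraction = 84 / 163,
                             balance_variables = c("pdl1_tc_status",
                                                   "response", "prior_lines",
                                                   "tumor_stage", "gender"),
                             seed = 1L, n_bins = 3L) {
  check_scalar_num(train_fraction, "train_fraction", lower = 1e-9,
                   upper = 1 - 1e-9)
  n <- nrow(cohort)
  check_that(n >= 2, "cohort must have >= 2 patients")

  strat <- cohort
  if ("pdl1_tc_status" %in% balance_variables &&
      !"pdl1_tc_status" %in% names(strat)) {
    check_that("pdl1_tc_pct" %in% names(strat),
               "'pdl1_tc_pct' column required to derive pdl1_tc_status")
    strat$pdl1_tc_status <- classify(strat$pdl1_tc_pct, 25)
  }
  check_that(all(balance_variables %in% names(strat)),
             paste("missing balance variables:",
                   paste(setdiff(balance_variables, names(strat)),
                         collapse = ", ")))
  keyparts <- lapply(balance_variables, function(v) {
    x <- strat[[v]]
    if (is.numeric(x) && length(unique(x)) > 6) {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
      x <- cut(x, breaks = br, include.lowest = TRUE)
    }
    as.character(x)
  })
  key <- do.call(paste, c(keyparts, sep = "|"))

  n_train <- round(train_fraction * n)
  sizes <- table(key)
  quota <- as.numeric(sizes) * n_train / n
  base <- floor(quota)
  rem <- quota - base
  extra <- n_train - sum(base)
  take <- base
  if (extra > 0) {
    ord <- order(-rem, seq_along(rem))  # largest remainder, stable
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  }
  take <- pmin(take, as.numeric(sizes))
  names(take) <- names(sizes)

  train_idx <- withr::with_seed(seed, {
    unlist(lapply(names(sizes), function(s) {
      rows <- which(key == s)
      rows <- rows[sample.int(length(rows))]
      rows[seq_len(take[[s]])]
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = cohort[train_idx, , drop = FALSE],
       test = cohort[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

measure_defs <- function() {
  data.frame(
    measure = c("CD8xPD-L1", "CD8+ cell density", "PD-L1+ cell density",
                "PD-L1 TC"),
    label_col = c("signature_label", "cd8_label", "pdl1_label",
                  "pdl1_tc_label"),
    pos_name = c("positive", "high", "high", ">=25%"),
    neg_name = c("negative", "low", "low", "<25%"),
    stringsAsFactors = FALSE
  )
}

#' Stratification performance table
#'
#' One row pair per measure (signature, CD8+ density, PD-L1+ density,
#' manual PD-L1 TC): group size, prevalence, PPV (= ORR in the group) with
#' exact binomial CI, median OS and PFS with CIs, and the two-group
#' log-rank p-values for OS and PFS (repeated on both rows of a pair).
#'
#' @param cohort cohort data.frame (labeled by [label_cohort()] if label
#'   columns are absent).
#' @param cutoffs a [cutoff_spec()] used when labeling is needed.
#' @param confidence confidence level for PPV intervals.
#' @return a data.frame with one row per measure-group.
#' @export
performance_table <- function(cohort, cutoffs = cutoff_spec(),
                              confidence = 0.95) {
  defs <- measure_defs()
  if (!all(defs$label_col %in% names(cohort))) {
    cohort <- label_cohort(cohort, cutoffs)
  }
  n <- nrow(cohort)
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    lc <- defs$label_col[i]
    pos <- cohort[[lc]] == "positive"
    p_os <- NA_real_; p_pfs <- NA_real_
    if (any(pos) && any(!pos)) {
      p_os <- logrank(cohort$os_time[pos], cohort$os_event[pos],
                      cohort$os_time[!pos], cohort$os_event[!pos])$p_value
      p_pfs <- logrank(cohort$pfs_time[pos], cohort$pfs_event[pos],
                       cohort$pfs_time[!pos], cohort$pfs_event[!pos])$p_value
    }
    for (grp in c(TRUE, FALSE)) {
      sel <- if (grp) pos else !pos
      ng <- sum(sel)
      ppv <- list(ppv = NA_real_, lo = NA_real_, hi = NA_real_)
      med_os <- list(median = NA_real_, ci = c(NA_real_, NA_real_))
      med_pfs <- med_os
      if (ng > 0) {
        ppv <- ppv_with_ci(ng, sum(cohort$response[sel]), confidence)
        med_os <- km_median(km_curve(cohort$os_time[sel],
                                     cohort$os_event[sel]))
        med_pfs <- km_median(km_curve(cohort$pfs_time[sel],
                                      cohort$pfs_event[sel]))
      }
      rows[[length(rows) + 1]] <- data.frame(
        measure = defs$measure[i],
        group = if (grp) defs$pos_name[i] else defs$neg_name[i],
        n = ng,
        prevalence = ng / n,
        ppv = ppv$ppv, ppv_lo = ppv$lo, ppv_hi = ppv$hi,
        median_os = med_os$median,
        median_os_lo = med_os$ci[1], median_os_hi = med_os$ci[2],
        p_os = p_os,
        median_pfs = med_pfs$median,
        median_pfs_lo = med_pfs$ci[1], median_pfs_hi = med_pfs$ci[2],
        p_pfs = p_pfs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Prepare a covariate data.frame for Cox fitting: characters become
# factors (first level = reference); positive/negative labels become 0/1
# indicators with negative as reference.
encode_covariates <- function(cohort, covariate_names) {
  out <- lapply(covariate_names, function(v) {
    x <- cohort[[v]]
    check_that(!is.null(x), sprintf("covariate '%s' missing from cohort", v))
    if (is.character(x)) {
      if (all(x %in% c("positive", "negative"))) {
        as.integer(x == "positive")
      } else {
        factor(x)
      }
    } else x
  })
  names(out) <- covariate_names
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Multiparametric Cox table
#'
#' For each added measure, fits the Cox OS model with the seven fixed
#' clinical covariates plus that measure (eight covariates total), bands
#' the added covariate's Wald p-value, lists which fixed covariates are
#' significant (p <= 0.05), and bands the whole-model improvement over the
#' fixed-covariates-only model via the nested likelihood-ratio test.
#'
#' @param cohort labeled cohort data.frame.
#' @param added_covariates columns to add one at a time (default: the four
#'   measure label columns).
#' @param fixed_covariates the fixed clinical covariate columns.
#' @param tie_method passed to [cox_fit()].
#' @return a data.frame: `added_covariate`, `p_added`, `band_added`,
#'   `significant_fixed_covariates` (comma-separated `name(band)`),
#'   `p_model`, `band_model`, `converged`.
#' @export
cox_table <- function(cohort,
                      added_covariates = c("signature_label", "cd8_label",
                                           "pdl1_label", "pdl1_tc_label"),
                      fixed_covariates = c("histology", "smoking_status",
                                           "age", "gender",
                                           "liver_metastasis", "tumor_stage",
                                           "prior_lines"),
                      tie_method = "efron") {
  fixed_df <- encode_covariates(cohort, fixed_covariates)
  fit_fixed <- cox_fit(fixed_df, cohort$os_time, cohort$os_event,
                       tie_method = tie_method)
  rows <- lapply(added_covariates, function(v) {
    add_df <- encode_covariates(cohort, v)
    full_df <- cbind(fixed_df, add_df)
    fit_full <- cox_fit(full_df, cohort$os_time, cohort$os_event,
                        tie_method = tie_method)
    # coefficient(s) belonging to the added covariate
    added_coef <- setdiff(names(fit_full$coefficients),
                          names(fit_fixed$coefficients))
    p_added <- min(fit_full$p_values[added_coef])
    fixed_p <- fit_full$p_values[names(fit_fixed$coefficients)]
    sig <- fixed_p[fixed_p <= 0.05 & !is.na(fixed_p)]
    sig_str <- if (length(sig) == 0) "" else
      paste(sprintf("%s(%s)", names(sig), significance_band(sig)),
            collapse = ", ")
    nested <- nested_lr_test(fit_fixed, fit_full)
    data.frame(
      added_covariate = v,
      p_added = p_added,
      band_added = significance_band(p_added),
      significant_fixed_covariates = sig_str,
      p_model = nested$p_value,
      band_model = significance_band(nested$p_value),
      converged = fit_full$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full signature analysis on a cohort pair
#'
#' Convenience driver: splits the treated cohort, learns the signature
#' cutoff on the training set by PPV maximization, evaluates the
#' performance tables on train and test at the learned cutoff (never
#' re-fit on test), computes the combined signature-positive prevalence,
#' and transfers positivity to an independent cohort by prevalence
#' matching.
#'
#' @param treated treated-cohort data.frame.
#' @param independent independent (non-ICT) cohort data.frame.
#' @param constraints a [search_constraints()].
#' @param train_fraction,seed passed to [stratified_split()].
#' @return a list: `split`, `search` (cutoff_search_result), `cutoffs`
#'   (cutoff_spec with the learned signature cutoff), `table_train`,
#'   `table_test`, `combined_prevalence`, `transfer` (transfer_result).
#' @export
run_signature_analysis <- function(treated, independent,
                                   constraints = search_constraints(),
                                   train_fraction = 84 / 163, seed = 1L) {
  treated$signature_score <- compute_score(treated$cd8_density,
                                           treated$pdl1_density)
  sp <- stratified_split(treated, train_fraction, seed = seed)
  search <- optimize_cutoff(sp$train, sp$train$signature_score, constraints)
  check_that(!is.null(search$best),
             "no feasible signature cutoff on the training set")
  cutoffs <- cutoff_spec(signature_cutoff = search$best$cutoff)
  table_train <- performance_table(label_cohort(sp$train, cutoffs), cutoffs)
  table_test <- performance_table(label_cohort(sp$test, cutoffs), cutoffs)

  combined <- label_cohort(rbind(sp$train, sp$test), cutoffs)
  q <- reference_prevalence(combined$signature_label)
  ind_scores <- compute_score(independent$cd8_density,
                              independent$pdl1_density)
  transfer <- match_prevalence(ind_scores, q)

  list(split = sp, search = search, cutoffs = cutoffs,
       table_train = table_train, table_test = table_test,
       combined_prevalence = q, transfer = transfer)
}
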