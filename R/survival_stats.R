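#' Kaplan-Meier curve
#'
#' Product-limit estimate with Greenwood variance and log-log pointwise
#' 95% confidence bands (the band transform also drives the median CI).
#'
#' @param times event/censoring times in months (> 0).
#' @param events 0/1 event indicators.
#' @return an object of class `km_curve`: `event_times`, `survival`,
#'   `ci_lower`, `ci_upper`, `n_risk`, `n_events`, and the underlying
#'   `survival::survfit` object as `fit`.
#' @export
km_curve <- function(times, events) {
  check_that(length(times) > 0 && length(times) == length(events),
             "'times' and 'events' must be non-empty and equal length")
  check_that(all(is.finite(times)) && all(times > 0),
             "'times' must be positive and finite")
  check_flag01(events, "events")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  structure(list(
    event_times = fit$time,
    survival = fit$surv,
    ci_lower = fit$lower,
    ci_upper = fit$upper,
    n_risk = fit$n.risk,
    n_events = fit$n.event,
    fit = fit
  ), class = "km_curve")
}

#' Median survival with confidence interval
#'
#' First time the survival curve drops to 0.5 or below; `NA` is the
#' not-reached sentinel. The CI inverts the log-log confidence band
#' (Brookmeyer-Crowley construction).
#'
#' @param curve a [km_curve()] object.
#' @return a list: `median` (months or NA = not reached), `ci`
#'   (length-2, NA where not reached).
#' @export
km_median <- function(curve) {
  check_that(inherits(curve, "km_curve"), "'curve' must come from km_curve()")
  hit <- which(curve$survival <= 0.5 + 1e-12)
  med <- if (length(hit) == 0) NA_real_ else curve$event_times[min(hit)]
  q <- stats::quantile(curve$fit, probs = 0.5)
  list(median = med,
       ci = c(unname(q$lower), unname(q$upper)))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square with 1 degree of freedom.
#'
#' @param times_a,events_a group A times and 0/1 events.
#' @param times_b,events_b group B times and 0/1 events.
#' @return a list: `statistic` (chi-square), `p_value`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  check_that(length(times_a) > 0 && length(times_b) > 0,
             "both groups must be non-empty")
  check_flag01(events_a, "events_a"); check_flag01(events_b, "events_b")
  check_that(sum(events_a) + sum(events_b) >= 1,
             "log-rank test undefined with zero events")
  t <- c(times_a, times_b)
  e <- c(events_a, events_b)
  g <- c(rep(0L, length(times_a)), rep(1L, length(times_b)))
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie handling by default;
#' Breslow optional) and reports Wald p-values. Non-convergence or a
#' monotone likelihood (perfect separation) is flagged rather than raised.
#'
#' @param covariates data.frame of covariates (factors are one-hot encoded
#'   against their first level) or a numeric matrix.
#' @param times,events survival times (months) and 0/1 events.
#' @param tie_method "efron" (default) or "breslow".
#' @return an object of class `cox_fit`: `coefficients`,
#'   `standard_errors`, `p_values` (named per encoded covariate),
#'   `log_partial_likelihood`, `null_log_partial_likelihood`, `n`,
#'   `n_events`, `converged`.
#' @export
cox_fit <- function(covariates, times, events,
                    tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  covariates <- as.data.frame(covariates, stringsAsFactors = TRUE)
  check_that(nrow(covariates) == length(times) &&
               length(times) == length(events),
             "covariates, times and events must have matching length")
  check_flag01(events, "events")
  for (nm in names(covariates)) {
    check_that(length(unique(covariates[[nm]])) > 1,
               sprintf("covariate '%s' is constant", nm))
  }
  dat <- covariates
  dat$..time <- times
  dat$..event <- events
  form <- stats::as.formula(paste(
    "survival::Surv(..time, ..event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))

  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = tie_method),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(fit$coefficients)) ||
      any(sqrt(diag(fit$var)) > 1e3)) {
    converged <- FALSE
  }
  se <- sqrt(diag(fit$var))
  zs <- fit$coefficients / se
  structure(list(
    coefficients = fit$coefficients,
    standard_errors = stats::setNames(se, names(fit$coefficients)),
    p_values = stats::setNames(
      2 * stats::pnorm(-abs(zs)), names(fit$coefficients)),
    log_partial_likelihood = fit$loglik[2],
    null_log_partial_likelihood = fit$loglik[1],
    n = fit$n, n_events = fit$nevent,
    converged = converged,
    tie_method = tie_method
  ), class = "cox_fit")
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' The "ANOVA" of two nested proportional-hazards fits: twice the
#' difference in maximized log partial likelihood, referred to a
#' chi-square with df = difference in parameter count.
#'
#' @param fit_reduced,fit_full [cox_fit()] objects on the same patients;
#'   the reduced model's covariates must be a subset of the full model's.
#' @return a list: `lr_statistic`, `df`, `p_value`.
#' @export
nested_lr_test <- function(fit_reduced, fit_full) {
  check_that(inherits(fit_reduced, "cox_fit") && inherits(fit_full, "cox_fit"),
             "both fits must come from cox_fit()")
  check_that(fit_reduced$n == fit_full$n &&
               fit_reduced$n_events == fit_full$n_events,
             "fits must be on the same patients")
  red <- names(fit_reduced$coefficients)
  ful <- names(fit_full$coefficients)
  check_that(all(red %in% ful), "models are not nested")
  df <- length(ful) - length(red)
  lr <- max(0, 2 * (fit_full$log_partial_likelihood -
                      fit_reduced$log_partial_likelihood))
  p <- if (df == 0) 1 else stats::pchisq(lr, df = df, lower.tail = FALSE)
  list(lr_statistic = lr, df = df, p_value = p)
}

#' Significance band of a p-value
#'
#' Four-symbol banding used in the report tables:
#' `-` for p > 0.05, `+` for p <= 0.05, `++` for p <= 0.005,
#' `+++` for p <= 0.0005 (boundaries inclusive on the <= side).
#'
#' @param p_value a p-value in (0, 1]; vectorized.
#' @return character vector of band symbols.
#' @export
significance_band <- function(p_value) {
  check_that(is.numeric(p_value) && all(is.finite(p_value)) &&
               all(p_value > 0 & p_value <= 1),
             "'p_value' must be in (0, 1]")
  ifelse(p_value <= 0.0005, "+++",
         ifelse(p_value <= 0.005, "++",
                ifelse(p_value <= 0.05, "+", "-")))
}
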