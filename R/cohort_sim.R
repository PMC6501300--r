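#' Configuration for a synthetic patient cohort
#'
#' Defines the generative model for a cohort of immunotherapy-treated (or
#' control) NSCLC patients: correlated log-normal CD8+ and PD-L1+ cell
#' densities, objective response drawn from a logistic model on the
#' standardized log product signature, and exponential proportional-hazards
#' survival for OS and PFS with independent exponential censoring.
#'
#' @param n_patients number of patients to simulate.
#' @param log_mean_cd8,log_sd_cd8 mean and sd of log CD8+ density
#'   (densities in cells/mm2).
#' @param log_mean_pdl1,log_sd_pdl1 mean and sd of log PD-L1+ density.
#' @param density_correlation correlation of the two log densities, in
#'   \[-1, 1\].
#' @param response_intercept,response_slope logistic-model coefficients on
#'   the standardized log signature; the intercept is on the logit scale.
#' @param baseline_hazard_os,baseline_hazard_pfs baseline event hazards in
#'   events/month at the covariate reference (signature at its cohort mean,
#'   no liver metastasis).
#' @param log_hr_signature log hazard ratio of the signature-high group
#'   (log score above the cohort median) versus the rest
#'   (negative = protective).
#' @param log_hr_liver_met log hazard ratio for liver metastasis.
#' @param covariate_prevalences named list of category probabilities for
#'   the clinical covariates (histology, smoking_status, gender,
#'   tumor_stage, liver_metastasis, prior_lines).
#' @param censor_rate hazard of independent censoring, events/month.
#' @param seed integer seed; the generator touches no global RNG state.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 163,
                          log_mean_cd8 = log(200), log_sd_cd8 = 1.0,
                          log_mean_pdl1 = log(300), log_sd_pdl1 = 1.1,
                          density_correlation = 0.4,
                          response_intercept = logit(0.10),
                          response_slope = 1.2,
                          baseline_hazard_os = log(2) / 9,
                          baseline_hazard_pfs = log(2) / 2.5,
                          log_hr_signature = log(7.8 / 21),
                          log_hr_liver_met = log(2.5),
                          covariate_prevalences = default_covariate_prevalences(),
                          censor_rate = 0.03,
                          seed = 1L) {
  check_scalar_num(n_patients, "n_patients", lower = 1)
  check_that(n_patients == round(n_patients),
             "'n_patients' must be a whole number")
  check_scalar_num(log_mean_cd8, "log_mean_cd8")
  check_scalar_num(log_sd_cd8, "log_sd_cd8")
  check_that(log_sd_cd8 > 0, "'log_sd_cd8' must be > 0")
  check_scalar_num(log_mean_pdl1, "log_mean_pdl1")
  check_scalar_num(log_sd_pdl1, "log_sd_pdl1")
  check_that(log_sd_pdl1 > 0, "'log_sd_pdl1' must be > 0")
  check_scalar_num(density_correlation, "density_correlation",
                   lower = -1, upper = 1)
  check_scalar_num(response_intercept, "response_intercept")
  check_scalar_num(response_slope, "response_slope")
  check_that(baseline_hazard_os > 0, "'baseline_hazard_os' must be > 0")
  check_that(baseline_hazard_pfs > 0, "'baseline_hazard_pfs' must be > 0")
  check_scalar_num(log_hr_signature, "log_hr_signature")
  check_scalar_num(log_hr_liver_met, "log_hr_liver_met")
  check_that(censor_rate > 0, "'censor_rate' must be > 0")
  check_covariate_prevalences(covariate_prevalences)
  check_scalar_num(seed, "seed")

  structure(list(
    n_patients = as.integer(n_patients),
    log_mean_cd8 = log_mean_cd8, log_sd_cd8 = log_sd_cd8,
    log_mean_pdl1 = log_mean_pdl1, log_sd_pdl1 = log_sd_pdl1,
    density_correlation = density_correlation,
    response_intercept = response_intercept,
    response_slope = response_slope,
    baseline_hazard_os = baseline_hazard_os,
    baseline_hazard_pfs = baseline_hazard_pfs,
    log_hr_signature = log_hr_signature,
    log_hr_liver_met = log_hr_liver_met,
    covariate_prevalences = covariate_prevalences,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default clinical covariate category probabilities
#'
#' Typical advanced-NSCLC trial marginals: mostly adenocarcinoma, a
#' majority of ever-smokers and males, predominantly stage IV, about a
#' quarter with liver metastases, and one to three prior therapy lines.
#'
#' @return a named list of probability vectors.
#' @export
default_covariate_prevalences <- function() {
  list(
    histology = c(adenocarcinoma = 0.55, squamous = 0.35, other = 0.10),
    smoking_status = c(never = 0.20, former = 0.50, current = 0.30),
    gender = c(female = 0.35, male = 0.65),
    tumor_stage = c(III = 0.30, IV = 0.70),
    liver_metastasis = 0.25,
    prior_lines = c(`1` = 0.35, `2` = 0.40, `3` = 0.25)
  )
}

check_covariate_prevalences <- function(cp) {
  needed <- c("histology", "smoking_status", "gender", "tumor_stage",
              "liver_metastasis", "prior_lines")
  check_that(is.list(cp) && all(needed %in% names(cp)),
             paste("'covariate_prevalences' must name:",
                   paste(needed, collapse = ", ")))
  for (nm in needed) {
    p <- cp[[nm]]
    check_that(is.numeric(p) && all(p >= 0 & p <= 1),
               sprintf("'covariate_prevalences$%s' must be probabilities in [0,1]", nm))
    if (nm != "liver_metastasis") {
      check_that(abs(sum(p) - 1) < 1e-8,
                 sprintf("'covariate_prevalences$%s' must sum to 1", nm))
    }
  }
  invisible(TRUE)
}

#' Simulate a patient cohort
#'
#' Draws a cohort from the model described in [cohort_config()]. Densities
#' come from a bivariate log-normal; response from a logistic model on the
#' standardized log product of the two densities; OS and PFS from
#' exponential proportional hazards driven by a signature-high indicator
#' (log score above the cohort median) and liver metastasis, with PFS
#' capped at OS so progression
#' never postdates death; censoring is independent exponential. The manual
#' PD-L1 tumor-cell percentage is a noisy monotone transform of PD-L1+
#' density, so the two measures correlate without being redundant.
#'
#' @param config a [cohort_config()] object.
#' @return a data.frame with one row per patient and columns
#'   `patient_id`, `cd8_density`, `pdl1_density`, `pdl1_tc_pct`,
#'   `response`, `os_time`, `os_event`, `pfs_time`, `pfs_event`,
#'   `histology`, `smoking_status`, `gender`, `tumor_stage`, `age`,
#'   `liver_metastasis`, `prior_lines`. Times are months; events are 0/1.
#' @export
generate_cohort <- function(config) {
  check_that(inherits(config, "cohort_config"),
             "'config' must be created by cohort_config()")
  n <- config$n_patients
  withr::with_seed(config$seed, {
    sig <- matrix(c(config$log_sd_cd8^2,
                    config$density_correlation * config$log_sd_cd8 * config$log_sd_pdl1,
                    config$density_correlation * config$log_sd_cd8 * config$log_sd_pdl1,
                    config$log_sd_pdl1^2), 2, 2)
    ld <- MASS::mvrnorm(n, mu = c(config$log_mean_cd8, config$log_mean_pdl1),
                        Sigma = sig)
    ld <- matrix(ld, ncol = 2)            # mvrnorm drops dims at n = 1
    cd8 <- exp(ld[, 1])
    pdl1 <- exp(ld[, 2])

    log_score <- log(cd8 * pdl1)
    s <- stats::sd(log_score)
    z <- if (is.na(s) || s == 0) rep(0, n) else (log_score - mean(log_score)) / s

    p_resp <- stats::plogis(config$response_intercept + config$response_slope * z)
    response <- stats::rbinom(n, 1L, p_resp)

    cp <- config$covariate_prevalences
    histology <- sample(names(cp$histology), n, TRUE, cp$histology)
    smoking <- sample(names(cp$smoking_status), n, TRUE, cp$smoking_status)
    gender <- sample(names(cp$gender), n, TRUE, cp$gender)
    stage <- sample(names(cp$tumor_stage), n, TRUE, cp$tumor_stage)
    liver <- stats::rbinom(n, 1L, cp$liver_metastasis)
    prior <- as.integer(sample(names(cp$prior_lines), n, TRUE, cp$prior_lines))
    age <- round(pmin(pmax(stats::rnorm(n, 64, 9), 30), 90))

    sig_high <- as.integer(log_score > stats::median(log_score))
    lp <- config$log_hr_signature * sig_high + config$log_hr_liver_met * liver
    t_os <- stats::rexp(n, config$baseline_hazard_os * exp(lp))
    t_pfs <- pmin(stats::rexp(n, config$baseline_hazard_pfs * exp(lp)), t_os)
    cens <- stats::rexp(n, config$censor_rate)
    os_time <- pmin(t_os, cens)
    os_event <- as.integer(t_os <= cens)
    pfs_time <- pmin(t_pfs, cens)
    pfs_event <- as.integer(t_pfs <= cens)

    # Manual tumor-cell % ~ logistic transform of log density + reader noise
    tc <- 100 * stats::plogis((log1p(pdl1) - 5.7) / 0.8 + stats::rnorm(n, 0, 0.5))

    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      cd8_density = cd8,
      pdl1_density = pdl1,
      pdl1_tc_pct = tc,
      response = response,
      os_time = os_time, os_event = os_event,
      pfs_time = pfs_time, pfs_event = pfs_event,
      histology = histology,
      smoking_status = smoking,
      gender = gender,
      tumor_stage = stage,
      age = age,
      liver_metastasis = liver,
      prior_lines = prior,
      stringsAsFactors = FALSE
    )
  })
}

#' Write / read a cohort as CSV
#'
#' Plain CSV with the fixed column set of [generate_cohort()]; categorical
#' covariates as strings, events as 0/1.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
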