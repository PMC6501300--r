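#' The CD8xPD-L1 product signature
#'
#' The signature score of a patient is the product of the CD8+ and PD-L1+
#' cell densities measured in the annotated tumor region, in cells2/mm4.
#'
#' @param cd8_density CD8+ cell density, cells/mm2 (>= 0).
#' @param pdl1_density PD-L1+ cell density, cells/mm2 (>= 0).
#' @return the score(s), cells2/mm4; vectorized.
#' @export
compute_score <- function(cd8_density, pdl1_density) {
  check_that(is.numeric(cd8_density) && all(is.finite(cd8_density)) &&
               all(cd8_density >= 0),
             "'cd8_density' must be finite and >= 0")
  check_that(is.numeric(pdl1_density) && all(is.finite(pdl1_density)) &&
               all(pdl1_density >= 0),
             "'pdl1_density' must be finite and >= 0")
  cd8_density * pdl1_density
}

#' Dichotomize a measure at a cutoff
#'
#' Boundary convention: a value equal to the cutoff is positive
#' (mirroring the "TC >= 25%" labeling of the manual PD-L1 score, applied
#' uniformly to all measures).
#'
#' @param value numeric vector.
#' @param cutoff positive scalar.
#' @return character vector, "positive" or "negative".
#' @export
classify <- function(value, cutoff) {
  check_that(is.numeric(cutoff) && length(cutoff) == 1 && cutoff > 0,
             "'cutoff' must be a positive scalar")
  ifelse(value >= cutoff, "positive", "negative")
}

#' Cutoff set for the four stratification measures
#'
#' Defaults are the published values: 297 cells/mm2 for CD8+ density,
#' 644 cells/mm2 for PD-L1+ density, 1.54e5 cells2/mm4 for the CD8xPD-L1
#' signature and 25% for the manual PD-L1 tumor-cell score. Note the
#' signature cutoff is learned independently and is not the product of the
#' component cutoffs (297 x 644 = 191268 > 1.54e5).
#'
#' @param cd8_cutoff,pdl1_cutoff,signature_cutoff,pdl1_tc_cutoff positive
#'   scalars in the units above.
#' @return a named list of class `cutoff_spec`.
#' @export
cutoff_spec <- function(cd8_cutoff = 297, pdl1_cutoff = 644,
                        signature_cutoff = 1.54e5, pdl1_tc_cutoff = 25) {
  for (nm in c("cd8_cutoff", "pdl1_cutoff", "signature_cutoff",
               "pdl1_tc_cutoff")) {
    v <- get(nm)
    check_that(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
               sprintf("'%s' must be a positive scalar", nm))
  }
  structure(list(cd8_cutoff = cd8_cutoff, pdl1_cutoff = pdl1_cutoff,
                 signature_cutoff = signature_cutoff,
                 pdl1_tc_cutoff = pdl1_tc_cutoff),
            class = "cutoff_spec")
}

#' Add signature score and positivity labels to a cohort
#'
#' Appends `signature_score` and one `<measure>_label` column per measure
#' ("positive"/"negative" at the supplied cutoffs).
#'
#' @param cohort cohort data.frame with `cd8_density`, `pdl1_density`,
#'   `pdl1_tc_pct` columns.
#' @param cutoffs a [cutoff_spec()].
#' @return the cohort with added columns.
#' @export
label_cohort <- function(cohort, cutoffs = cutoff_spec()) {
  check_that(inherits(cutoffs, "cutoff_spec"),
             "'cutoffs' must come from cutoff_spec()")
  cohort$signature_score <- compute_score(cohort$cd8_density,
                                          cohort$pdl1_density)
  cohort$signature_label <- classify(cohort$signature_score,
                                     cutoffs$signature_cutoff)
  cohort$cd8_label <- classify(cohort$cd8_density, cutoffs$cd8_cutoff)
  cohort$pdl1_label <- classify(cohort$pdl1_density, cutoffs$pdl1_cutoff)
  cohort$pdl1_tc_label <- classify(cohort$pdl1_tc_pct,
                                   cutoffs$pdl1_tc_cutoff)
  cohort
}
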