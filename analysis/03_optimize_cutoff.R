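#!/usr/bin/env Rscript
# Splits the treated cohort 84/79 balanced on PD-L1 status, response,
# prior lines, stage and gender, then learns the signature cutoff on the
# training set by PPV maximization under the log-rank (OS and PFS p <=
# 0.05) and prevalence (30-70%) constraints.
source("analysis/00_common.R")

treated <- read_cohort(res_path("cohort_treated.csv"))
treated$signature_score <- compute_score(treated$cd8_density,
                                         treated$pdl1_density)
sp <- stratified_split(treated, train_fraction = 84 / 163,
                       seed = ANALYSIS_SEED)
write_cohort(sp$train, res_path("train.csv"))
write_cohort(sp$test, res_path("test.csv"))
message(sprintf("split: train n = %d, test n = %d",
                nrow(sp$train), nrow(sp$test)))

search <- optimize_cutoff(sp$train, sp$train$signature_score)
write.csv(search$all_evaluations, res_path("cutoff_search.csv"),
          row.names = FALSE)
stopifnot(!is.null(search$best))
message(sprintf(
  "signature cutoff %.3g cells2/mm4: prevalence %.2f, PPV %.2f (%.2f-%.2f), p_os %.3g, p_pfs %.3g",
  search$best$cutoff, search$best$prevalence, search$best$ppv,
  search$best$ppv_lo, search$best$ppv_hi, search$best$p_os,
  search$best$p_pfs))
jsonlite::write_json(as.list(search$best), res_path("chosen_cutoff.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", res_path("chosen_cutoff.json"))
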