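#!/usr/bin/env Rscript
# Evaluates the learned cutoff: stratification performance tables for the
# training and test sets (prevalence, PPV with exact CI, median OS/PFS
# with CIs, log-rank p-values) and the eight-covariate Cox table with
# nested-model banding on the combined cohort.
source("analysis/00_common.R")

train <- read_cohort(res_path("train.csv"))
test <- read_cohort(res_path("test.csv"))
chosen <- jsonlite::read_json(res_path("chosen_cutoff.json"),
                              simplifyVector = TRUE)
cutoffs <- cutoff_spec(signature_cutoff = chosen$cutoff)

tab_train <- performance_table(label_cohort(train, cutoffs), cutoffs)
tab_test <- performance_table(label_cohort(test, cutoffs), cutoffs)
write.csv(tab_train, res_path("performance_train.csv"), row.names = FALSE)
write.csv(tab_test, res_path("performance_test.csv"), row.names = FALSE)

sig <- tab_test[tab_test$measure == "CD8xPD-L1", ]
message(sprintf(
  "test set, signature: prevalence %.2f/%.2f, median OS %.1f vs %.1f months, p_os %.3g",
  sig$prevalence[1], sig$prevalence[2], sig$median_os[1], sig$median_os[2],
  sig$p_os[1]))

combined <- label_cohort(rbind(train, test), cutoffs)
ct <- cox_table(combined)
write.csv(ct, res_path("cox_table.csv"), row.names = FALSE)
message("Cox table (combined set, OS):")
for (i in seq_len(nrow(ct))) {
  message(sprintf("  %-16s added: %-4s model vs fixed-only: %-4s",
                  ct$added_covariate[i], ct$band_added[i], ct$band_model[i]))
}
message("wrote ", res_path("cox_table.csv"))
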