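#!/usr/bin/env Rscript
# Transfers signature positivity to the non-ICT cohort by matching the
# combined treated cohort's signature-positive prevalence, then checks
# whether the signature stratifies OS there (prognostic value).
source("analysis/00_common.R")

train <- read_cohort(res_path("train.csv"))
test <- read_cohort(res_path("test.csv"))
nonict <- read_cohort(res_path("cohort_nonict.csv"))
chosen <- jsonlite::read_json(res_path("chosen_cutoff.json"),
                              simplifyVector = TRUE)
cutoffs <- cutoff_spec(signature_cutoff = chosen$cutoff)

combined <- label_cohort(rbind(train, test), cutoffs)
q <- reference_prevalence(combined$signature_label)
message(sprintf("combined signature-positive prevalence: %.4f (%.0f%%)",
                q, 100 * q))

scores <- compute_score(nonict$cd8_density, nonict$pdl1_density)
tr <- match_prevalence(scores, q)
nonict$signature_score <- scores
nonict$signature_label <- tr$labels
write_cohort(nonict, res_path("cohort_nonict_labeled.csv"))
message(sprintf("non-ICT: %d of %d labeled positive; derived cutoff %.3g cells2/mm4",
                tr$n_positive, nrow(nonict), tr$derived_cutoff))

pos <- nonict$signature_label == "positive"
lr <- logrank(nonict$os_time[pos], nonict$os_event[pos],
              nonict$os_time[!pos], nonict$os_event[!pos])
message(sprintf("non-ICT OS log-rank p = %.3g (signature transferred, not re-fit)",
                lr$p_value))
jsonlite::write_json(
  list(matched_prevalence = tr$matched_prevalence,
       n_positive = tr$n_positive, derived_cutoff = tr$derived_cutoff,
       nonict_logrank_p_os = lr$p_value),
  res_path("transfer.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", res_path("transfer.json"))
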