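#!/usr/bin/env Rscript
# Simulates the two study cohorts -- 163 checkpoint-treated patients and
# 199 non-ICT controls -- plus a pair of single-stain IHC images with
# ground truth, and writes everything under results/.
source("analysis/00_common.R")

treated <- generate_cohort(cohort_config(n_patients = 163,
                                         seed = ANALYSIS_SEED))
# Non-ICT controls: the signature carries no survival effect without
# checkpoint therapy, and the surgical cohort has a far longer baseline
# median OS with lighter censoring.
nonict <- generate_cohort(cohort_config(n_patients = 199,
                                        log_hr_signature = 0,
                                        baseline_hazard_os = log(2) / 48,
                                        baseline_hazard_pfs = log(2) / 24,
                                        censor_rate = 0.01,
                                        seed = ANALYSIS_SEED + 1L))
write_cohort(treated, res_path("cohort_treated.csv"))
write_cohort(nonict, res_path("cohort_nonict.csv"))
message(sprintf("treated cohort: n = %d, ORR = %.2f, OS events = %d",
                nrow(treated), mean(treated$response), sum(treated$os_event)))
message(sprintf("non-ICT cohort: n = %d, OS events = %d",
                nrow(nonict), sum(nonict$os_event)))

for (stain in c("CD8", "PD-L1")) {
  sim <- generate_ihc_image(image_config(
    n_cells = if (stain == "CD8") 60 else 40, stain_name = stain,
    seed = ANALYSIS_SEED + if (stain == "CD8") 10L else 11L))
  tag <- tolower(gsub("-", "", stain))
  write_ihc_image(sim,
                  res_path(sprintf("image_%s.png", tag)),
                  res_path(sprintf("mask_%s.png", tag)),
                  res_path(sprintf("truth_%s.json", tag)))
  message(sprintf("%s image: %d cells over %.3f mm2 (true density %.0f /mm2)",
                  stain, sim$truth$count, sim$truth$mask_area_mm2,
                  sim$truth$true_density))
}
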