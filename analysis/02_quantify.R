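#!/usr/bin/env Rscript
# Quantifies the simulated IHC images: stain unmixing, cell detection,
# density in the tumor mask; compares against the rendered ground truth.
source("analysis/00_common.R")

rows <- lapply(c("cd8", "pdl1"), function(tag) {
  img <- read_rgb_png(res_path(sprintf("image_%s.png", tag)))
  mask <- read_mask_png(res_path(sprintf("mask_%s.png", tag)))
  truth <- jsonlite::read_json(res_path(sprintf("truth_%s.json", tag)),
                               simplifyVector = TRUE)
  q <- quantify_density(img, mask, truth$microns_per_pixel)
  message(sprintf("%s: detected %d of %d cells; density %.0f vs true %.0f cells/mm2",
                  tag, q$count, truth$count, q$density, truth$true_density))
  data.frame(stain = tag, n_true = truth$count, n_detected = q$count,
             area_mm2 = q$area_mm2, density = q$density,
             true_density = truth$true_density,
             rel_error = abs(q$density - truth$true_density) /
               truth$true_density)
})
quant <- do.call(rbind, rows)
write.csv(quant, res_path("quantification.csv"), row.names = FALSE)
message("wrote ", res_path("quantification.csv"))
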