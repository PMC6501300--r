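# Shared settings for the analysis drivers. Run the scripts in order from
# the repository root: Rscript analysis/01_simulate.R, 02_..., etc.
suppressMessages(library(cd8pdl1))

ANALYSIS_SEED <- 1108L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

res_path <- function(...) file.path(RESULTS_DIR, ...)
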