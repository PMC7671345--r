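# Shared settings for the analysis drivers. Every script can be run from
# the repository root in order (01, 02, ...); outputs accumulate under
# results/analysis/.

suppressPackageStartupMessages(library(hlapanel))

out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

analysis_seed <- 2024L
sim_cfg <- simulation_config(seed = analysis_seed)
run_cfg <- run_config(n_classifiers = 25L, seed = analysis_seed)
n_reference <- 800L
n_test <- 200L
n_target <- 2000L
n_batches <- 10L

path_of <- function(...) file.path(out_dir, paste0(...))
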