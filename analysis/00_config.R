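# Shared settings for the analysis workflow. Each numbered script sources
# this file, reads its inputs from results/, and writes its outputs there,
# so any stage can be rerun in isolation. Run the scripts from the package
# root, e.g. `Rscript analysis/01_simulate.R`.

suppressMessages(library(nichenull))

config <- list(
  seed = 20160914L,
  n_sites = 60L,
  n_species = 40L,
  n_gradients = 2L,
  n_env_vars = 4L,
  collinear_r2 = 0.99,
  mass_effect = 0.5,
  min_occurrences = 5L,
  n_replicates = 200L,
  n_trees = 100L,
  n_groups = 3L,
  n_perm = 999L
)

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
res_path <- function(...) file.path(results_dir, ...)
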