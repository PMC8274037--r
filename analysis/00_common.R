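# Shared setup for the numbered analysis scripts.
#
# Every script can be run on its own from the repository root:
#   Rscript analysis/01_simulate.R
# The full pipeline run is cached under scratch/ so later scripts do not
# recompute earlier stages; delete scratch/pipeline_report.rds to force a
# fresh run. Small human-readable result tables go to results/.

suppressPackageStartupMessages(library(mtbimeth))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

analysis_config <- function() {
  pipeline_config(synthetic = synthetic_config(seed = 7),
                  lambda_grid_length = 12, n_perm = 199, seed = 42)
}

get_report <- function() {
  cache <- "scratch/pipeline_report.rds"
  if (file.exists(cache)) return(readRDS(cache))
  rep <- suppressWarnings(run_pipeline(analysis_config()))
  saveRDS(rep, cache)
  rep
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
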