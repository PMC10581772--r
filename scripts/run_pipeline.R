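#!/usr/bin/env Rscript
# Thin shell entry point over beecology::run_pipeline(): simulates the
# configured colony and writes all analysis tables.
# Usage: Rscript scripts/run_pipeline.R --out-dir <dir> [--seed <int>]
#          [--n-bees <int>] [--days <n_control,n_stress>]

suppressMessages(library(beecology))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
out_dir <- arg_val("--out-dir", "pipeline-out")
seed <- as.integer(arg_val("--seed", "1"))
n_bees <- as.integer(arg_val("--n-bees", "40"))

cfg <- pipeline_config(sim = sim_config(
  n_bees = n_bees, rng_seed = seed,
  sim_days = data.frame(
    date = as.Date(c("2019-08-22", "2019-08-23")),
    is_stress = c(FALSE, TRUE))))
res <- run_pipeline(cfg, out_dir)
cat("pipeline outputs written to", normalizePath(out_dir), "\n")
cat("behavioural hours:", nrow(res$bm$matrix),
    "| bees:", length(unique(res$bm$info$bee_id)), "\n")
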