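#!/usr/bin/env Rscript

# Thin shell wrapper over primarytx::run_pipeline().
# Usage:
#   Rscript scripts/run-pipeline.R --out DIR [--seed N] [--config params.yaml]
# Without --config, a simulated dataset under the default study
# conditions is generated and annotated end to end.

suppressPackageStartupMessages(library(primarytx))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

cfg <- if (!is.null(get_arg("--config"))) {
  read_pipeline_config(get_arg("--config"))
} else {
  pipeline_config()
}
cfg$out_dir <- get_arg("--out", cfg$out_dir)
seed <- get_arg("--seed")
if (!is.null(seed)) cfg$seed <- as.integer(seed)

res <- run_pipeline(cfg)
cat("artifacts written to", res$out_dir, "\n")
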