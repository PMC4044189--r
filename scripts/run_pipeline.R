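#!/usr/bin/env Rscript

# Thin command-line wrapper over glasscoh::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R [--config config.yaml] [--seed 1]
#                                  [--out-dir DIR] [--n-runs 12]
#                                  [--n-participants 6] [--n-permutations 10000]
#
# A YAML config (written by glasscoh::write_pipeline_config()) overrides
# the defaults; individual flags override the config. Exit status: 0 on
# success, 1 on usage error, 2 on a stage failure.

suppressPackageStartupMessages({
  library(optparse)
  library(glasscoh)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline configuration file"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed"),
  make_option("--out-dir", type = "character", default = NULL,
              dest = "out_dir", help = "output directory"),
  make_option("--n-runs", type = "integer", default = NULL,
              dest = "n_runs", help = "runs per participant"),
  make_option("--n-participants", type = "integer", default = NULL,
              dest = "n_participants", help = "participants"),
  make_option("--n-permutations", type = "integer", default = NULL,
              dest = "n_permutations", help = "permutation iterations")))
opt <- tryCatch(parse_args(parser), error = function(e) {
  message(conditionMessage(e)); quit(status = 1)
})

cfg <- tryCatch({
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
         else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  if (!is.null(opt$out_dir)) cfg$output_dir <- opt$out_dir
  if (!is.null(opt$n_runs)) cfg$protocol$n_runs <- opt$n_runs
  if (!is.null(opt$n_participants)) cfg$n_participants <- opt$n_participants
  if (!is.null(opt$n_permutations)) cfg$n_permutations <- opt$n_permutations
  cfg
}, error = function(e) {
  message("configuration error: ", conditionMessage(e)); quit(status = 1)
})

tryCatch(invisible(run_pipeline(cfg)), error = function(e) {
  message("pipeline failure: ", conditionMessage(e)); quit(status = 2)
})
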