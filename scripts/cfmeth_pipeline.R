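#!/usr/bin/env Rscript
# Thin command-line wrapper over the cfmeth pipeline stages.
#
# Usage:
#   Rscript scripts/cfmeth_pipeline.R <stage>|run-all [--config cfg.yaml]
#                                     [--seed N] [--out DIR]
#
# Stages: simulate, summarize, dmr, cnv, deconv, classify, qc.

suppressPackageStartupMessages({
  library(optparse)
  library(cfmeth)
})

parser <- OptionParser(
  usage = "%prog <stage>|run-all [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML pipeline configuration"),
    make_option("--seed", type = "integer", default = NULL,
                help = "override the global seed"),
    make_option("--out", type = "character", default = NULL,
                help = "override the output directory")))
args <- parse_args(parser, positional_arguments = 1)
stage <- args$args

cfg <- if (is.null(args$options$config)) {
  pipeline_config()
} else {
  read_pipeline_config(args$options$config)
}
if (!is.null(args$options$seed)) cfg$seed <- args$options$seed
if (!is.null(args$options$out)) cfg$out_dir <- args$options$out

if (stage == "run-all") {
  run_pipeline(cfg)
} else {
  run_stage(stage, cfg)
}
message("done: ", stage, " -> ", cfg$out_dir)
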