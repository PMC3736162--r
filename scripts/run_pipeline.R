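#!/usr/bin/env Rscript
# Thin command-line wrapper around mdshsct::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --config config.yaml
#   Rscript scripts/run_pipeline.R --out demo-out --seed 2   # synthetic demo

suppressPackageStartupMessages(library(optparse))

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (see ?mdshsct::run_pipeline)"),
  make_option("--out", type = "character", default = "mdshsct-out",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "seed for all randomness [default %default]"),
  make_option("--scheme", type = "character", default = "IPSS",
              help = "risk scheme, IPSS or WPSS [default %default]")))
opt <- parse_args(parser)

library(mdshsct)
cfg <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
if (is.null(cfg$output_dir)) cfg$output_dir <- opt$out
if (is.null(cfg$seed)) cfg$seed <- opt$seed
if (is.null(cfg$scheme)) cfg$scheme <- opt$scheme

res <- run_pipeline(cfg)
cat("outputs written to", res$output_dir, "\n")
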