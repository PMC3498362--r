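#!/usr/bin/env Rscript
# Thin command-line wrapper over miRstress::run_pipeline():
#   Rscript scripts/run_pipeline.R --config config.yaml --out DIR [--seed N]
suppressPackageStartupMessages({
  library(optparse)
  library(miRstress)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", help = "YAML pipeline config"),
  make_option("--out", type = "character", help = "output directory"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config seed")
)))
if (is.null(opts$config) || is.null(opts$out)) {
  stop("--config and --out are required")
}
cfg <- pipeline_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed
run_pipeline(cfg, opts$out)
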