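#!/usr/bin/env Rscript

## Thin command-line wrapper around bltseq::run_pipeline().
##   Rscript scripts/blt.R --config <yaml> --out <dir> [--seed N]
##                         [--stages simulate,process,quantify,pcut,model,scan]

suppressMessages({
  library(optparse)
  library(bltseq)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--out", type = "character"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--stages", type = "character", default = "all")
)))
if (is.null(opts$config) || is.null(opts$out))
  stop("--config and --out are required", call. = FALSE)

stages <- if (identical(opts$stages, "all")) "all" else
  strsplit(opts$stages, ",", fixed = TRUE)[[1]]
run_pipeline(opts$config, opts$out, seed = opts$seed, stages = stages)
cat("pipeline finished; outputs in", opts$out, "\n")
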