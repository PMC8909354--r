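#!/usr/bin/env Rscript

# Thin command-line wrapper over immunoconcord::run_pipeline().
#
# Usage: Rscript scripts/pipeline.R [--config path.json] [--seed int]
#                                   [--out dir] [--subset all|cutoff20]

suppressPackageStartupMessages({
  library(optparse)
  library(immunoconcord)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "JSON configuration [default: packaged]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed [default: %default]"),
  make_option("--out", type = "character", default = "pipeline_out",
              help = "output directory [default: %default]"),
  make_option("--subset", type = "character", default = "all",
              help = "'all' or 'cutoff20' [default: %default]")
)))

t0 <- Sys.time()
m <- run_pipeline(config = opts$config, seed = opts$seed,
                  out_dir = opts$out, subset = opts$subset)
message(sprintf("pipeline finished in %.1f s; outputs in %s",
                as.numeric(Sys.time() - t0, units = "secs"), opts$out))
print(m)
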