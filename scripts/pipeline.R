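#!/usr/bin/env Rscript

# Thin command-line wrapper over mdmx::run_pipeline().
#
# Usage: Rscript scripts/pipeline.R [--config run.cfg] [--out report.json]

suppressPackageStartupMessages(library(mdmx))

args <- commandArgs(trailingOnly = TRUE)
getopt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
config_path <- getopt("--config")
out <- getopt("--out", "report.json")

config <- if (is.null(config_path)) {
  default_pipeline_config()
} else {
  read_pipeline_config(config_path)
}
report <- run_pipeline(config, out = out)
print(report)
if (length(report$errors)) quit(status = 1)
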