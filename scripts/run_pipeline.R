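#!/usr/bin/env Rscript
# Thin command-line wrapper over erfrag::run_pipeline(). Usage:
#   Rscript scripts/run_pipeline.R --config inst/extdata/demo_config.toml \
#     --out runs/demo --seed 1

suppressPackageStartupMessages({
  library(optparse)
  library(erfrag)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "TOML run configuration (default: built-in demo)"),
  make_option("--out", type = "character", default = "erfrag_run"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the configuration's seed"),
  make_option("--validate-only", action = "store_true", default = FALSE,
              dest = "validate_only")
)))

config <- if (is.null(opts$config)) {
  demo_config()
} else {
  read_toml(opts$config)
}

if (opts$validate_only) {
  problems <- validate_config(config)
  if (nrow(problems) == 0) {
    cat("configuration valid\n")
  } else {
    for (i in seq_len(nrow(problems))) {
      cat(sprintf("%s: %s\n", problems$field[i], problems$message[i]))
    }
    quit(status = 1)
  }
} else {
  summary <- run_pipeline(config, out_dir = opts$out, seed = opts$seed)
  cat("stages run:", paste(summary$stages_run, collapse = ", "), "\n")
  cat("summary written to", file.path(opts$out, "summary.json"), "\n")
}
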