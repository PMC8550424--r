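#!/usr/bin/env Rscript
# Thin command-line wrapper over the dalyvol pipeline stages.
#   Rscript scripts/dalyvol.R <simulate|aggregate|trend|volatility> [options]

suppressPackageStartupMessages({
  library(optparse)
  library(dalyvol)
})

usage <- "Rscript scripts/dalyvol.R <simulate|aggregate|trend|volatility> [options]"
args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "aggregate", "trend",
                                        "volatility")) {
  message(usage)
  quit(status = 2)
}
stage <- args[1]

parser <- OptionParser(usage = usage, option_list = list(
  make_option("--input", type = "character", default = NULL),
  make_option("--income-groups", type = "character", default = NULL,
              dest = "income_groups"),
  make_option("--years", type = "character", default = "1990,2017",
              help = "inclusive span, e.g. 1990,2017"),
  make_option("--degree", type = "integer", default = 3L),
  make_option("--interior-knots", type = "integer", default = 3L,
              dest = "interior_knots"),
  make_option("--lambda-grid", type = "character", default = NULL,
              dest = "lambda_grid",
              help = "comma-separated penalty values; default 61-point grid"),
  make_option("--convention", type = "character", default = "unit-penalty",
              help = "unit-penalty or literal-lambda"),
  make_option("--bootstrap-reps", type = "integer", default = 1000L,
              dest = "bootstrap_reps"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", type = "character", default = ".",
              dest = "out_dir")))
opt <- parse_args(parser, args = args[-1])

grid <- if (is.null(opt$lambda_grid)) default_lambda_grid() else
  as.numeric(strsplit(opt$lambda_grid, ",")[[1]])
cfg <- run_config(input = opt$input, income_groups = opt$income_groups,
                  out_dir = opt$out_dir,
                  years = as.integer(strsplit(opt$years, ",")[[1]]),
                  degree = opt$degree,
                  interior_knots = opt$interior_knots,
                  lambda_grid = grid, convention = opt$convention,
                  bootstrap_reps = opt$bootstrap_reps, seed = opt$seed)

status <- tryCatch({
  res <- switch(stage,
                simulate = cmd_simulate(cfg),
                aggregate = cmd_aggregate(cfg),
                trend = cmd_trend(cfg),
                volatility = cmd_volatility(cfg))
  for (p in Filter(is.character, res)) message("wrote ", p)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
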