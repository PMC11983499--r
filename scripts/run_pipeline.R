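#!/usr/bin/env Rscript
# Thin command-line wrapper over the mltctraj package.
#
#   Rscript scripts/run_pipeline.R simulate --n 2000 --seed 1 --out <dir>
#   Rscript scripts/run_pipeline.R run-all --diagnoses <csv> \
#       --demographics <csv> [--stays <csv>] [--deaths <csv>] \
#       [--config <yaml>] --out <dir>
#
# simulate writes a synthetic cohort (five CSVs + ground-truth JSON);
# run-all executes the full per-stratum analysis and writes every artifact
# plus a run manifest.

suppressPackageStartupMessages(library(mltctraj))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: run_pipeline.R {simulate|run-all} [--flag value ...]\n")
  quit(status = 2)
}
if (length(args) < 1L) usage()
cmd <- args[[1L]]
get_arg <- function(flag, default = NULL) {
  hit <- which(args == flag)
  if (length(hit) == 1L && hit < length(args)) args[hit + 1L] else default
}

if (cmd == "simulate") {
  out <- get_arg("--out"); if (is.null(out)) usage()
  spec <- cohort_spec(n_patients = as.integer(get_arg("--n", "2000")),
                      seed = as.integer(get_arg("--seed", "1")))
  cohort <- generate_cohort(spec)
  write_cohort(cohort, out)
  message("cohort written to ", out)
} else if (cmd == "run-all") {
  out <- get_arg("--out"); if (is.null(out)) usage()
  cfg_path <- get_arg("--config")
  config <- if (is.null(cfg_path)) default_run_config() else
    read_run_config(cfg_path)
  inputs <- load_inputs(get_arg("--diagnoses"), get_arg("--demographics"),
                        config)
  read_opt <- function(flag, empty) {
    path <- get_arg(flag)
    if (is.null(path)) return(empty)
    df <- read.csv(path, stringsAsFactors = FALSE)
    for (col in grep("date$", names(df), value = TRUE))
      df[[col]] <- as.Date(df[[col]])
    df
  }
  stays <- read_opt("--stays", mltctraj:::empty_stays())
  deaths <- read_opt("--deaths", mltctraj:::empty_deaths())
  res <- run_pipeline(inputs$diagnoses, inputs$profiles, stays, deaths,
                      config = config, out_dir = out)
  print(res)
  message("artifacts written to ", out)
} else {
  usage()
}
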