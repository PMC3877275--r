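#!/usr/bin/env Rscript

# Thin command-line front-end over the growthscape package.
#
# Usage:
#   Rscript scripts/growthscape.R synth --regime warm|cold --n-stations N \
#       --seed S --out DIR
#   Rscript scripts/growthscape.R all   --regime warm|cold --n-stations N \
#       --seed S --out DIR [--n-fish N] [--hours H] [--eta E]
#
# `synth` writes a survey bundle; `all` runs the full pipeline
# (synth -> prep -> bioenergetics -> IBM -> sensitivity -> comparison).

suppressPackageStartupMessages(library(growthscape))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || args[1] %in% c("-h", "--help")) {
  cat("usage: growthscape.R <synth|all> [--regime warm|cold]",
      "[--n-stations N] [--seed S] [--out DIR] [--n-fish N] [--hours H]",
      "[--eta E]\n")
  quit(status = if (length(args) < 1) 1 else 0)
}
cmd <- args[1]
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
regime <- get_arg("--regime", "warm")
n_stations <- as.integer(get_arg("--n-stations", "30"))
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "growthscape_out")

if (cmd == "synth") {
  bundle <- make_scenario(scenario_config(regime, n_stations = n_stations,
                                          seed = seed))
  write_bundle(bundle, out)
  cat("wrote bundle to", out, "\n")
} else if (cmd == "all") {
  res <- suppressWarnings(run_pipeline(
    out, regime = regime, n_stations = n_stations, seed = seed,
    n_fish = as.integer(get_arg("--n-fish", "100")),
    hours = as.integer(get_arg("--hours", "72")),
    eta = as.numeric(get_arg("--eta", "1"))
  ))
  cat("pipeline complete; outputs in", out, "\n")
  print(res$comparison)
} else {
  cat("unknown subcommand:", cmd, "\n")
  quit(status = 1)
}
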