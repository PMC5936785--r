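# Shared helpers for the numbered analysis drivers. Each driver is run as
#   Rscript analysis/NN_name.R [--seed <int>] [--out <dir>]
# and reads the outputs of earlier stages from the same --out directory.

library(ventriflow)

cli_arg <- function(flag, default = NULL) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}

run_seed <- function() as.integer(cli_arg("--seed", "1"))

out_dir <- function() {
  d <- cli_arg("--out", "analysis/output")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

stage_path <- function(dir, name) file.path(dir, name)

need_stage <- function(dir, name, producer) {
  p <- stage_path(dir, name)
  if (!file.exists(p))
    stop(name, " not found in ", dir, "; run ", producer, " first",
         call. = FALSE)
  readRDS(p)
}
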