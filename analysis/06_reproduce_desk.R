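# Stage 6: the whole paired study in one call -- equivalent to running
# stages 1-4 back to back with the defaults (standalone; ~15 minutes).

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

out <- out_dir()
ds <- reproduce_desk(seed = run_seed(), progress = TRUE)
print(ds)

write_summary_json(list(
  seed = ds$seed,
  q_threshold = ds$q_threshold,
  smoothed = unclass(ds$summary_smoothed),
  detailed = unclass(ds$summary_detailed),
  error_smoothed = as.list(ds$error_smoothed),
  comparisons = as.list(ds$comparisons)),
  stage_path(out, "desk_study.json"))
write.csv(ds$sweep$grid, stage_path(out, "desk_sweep.csv"),
          row.names = FALSE)
saveRDS(ds, stage_path(out, "06_desk_study.rds"))
message("wrote ", out, "/06_desk_study.rds (+ desk_study.json, desk_sweep.csv)")
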