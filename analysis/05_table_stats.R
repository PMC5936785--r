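# Stage 5: recompute the derived statistics of the packaged study tables
# (standalone; needs no earlier stage).

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

out <- out_dir()
st <- table_stats()

message("per-heart pressure-drop difference, detailed - smoothed (kPa):")
print(round(st$delta_p_diff, 3))
message(sprintf("mean over hearts A/B/C/E: %.3g kPa", st$mean_delta_p_diff_abce))
message(sprintf("vortex surface means: smoothed %.4g m^2, detailed %.4g m^2",
                st$vortex_mean_smoothed, st$vortex_mean_detailed))
message(sprintf("WSS median reduction range: %.1f%% to %.1f%%",
                st$wss_reduction_range[1], st$wss_reduction_range[2]))

tb <- study_tables()$table1
area_d <- tb$value[tb$quantity == "area_inlet_m2" & tb$heart == "D"]
message(sprintf("inlet Reynolds, heart D (area %.3g m^2, 0.55 m/s): %.0f",
                area_d, inlet_reynolds(area_d, 0.55)))

write_summary_json(list(
  delta_p_diff = as.list(st$delta_p_diff),
  mean_delta_p_diff_abce = st$mean_delta_p_diff_abce,
  vortex_mean_smoothed = st$vortex_mean_smoothed,
  vortex_mean_detailed = st$vortex_mean_detailed,
  wss_reduction_range = st$wss_reduction_range,
  reynolds_model_d = inlet_reynolds(area_d, 0.55)),
  stage_path(out, "table_stats.json"))
message("wrote ", out, "/table_stats.json")
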