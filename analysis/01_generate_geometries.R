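# Stage 1: build the paired smoothed / trabeculated cavity surfaces for one
# seed, compute their geometry markers, and export surfaces + markers.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

seed <- run_seed()
out <- out_dir()

params <- cavity_params()
smoothed <- build_smoothed_cavity(params)
trab <- trabeculation_params(target_volume_fraction = 0.30, seed = seed)
detailed <- add_trabeculation(smoothed, trab)

markers <- list(smoothed = compute_markers(smoothed),
                detailed = compute_markers(detailed))
message(sprintf("smoothed cavity volume %.1f mL, detailed %.1f mL (trabeculae %.1f%%)",
                1e6 * markers$smoothed$cavity_volume,
                1e6 * markers$detailed$cavity_volume,
                markers$detailed$trabecular_volume_pct))

write_mesh(smoothed, stage_path(out, "smoothed.stl"), binary = TRUE)
write_mesh(detailed, stage_path(out, "detailed.stl"), binary = TRUE)
write_summary_json(lapply(markers, unclass),
                   stage_path(out, "markers.json"))
saveRDS(list(seed = seed, params = params, trab = trab,
             smoothed = smoothed, detailed = detailed, markers = markers),
        stage_path(out, "01_geometries.rds"))
message("wrote ", out, "/01_geometries.rds (+ STL surfaces, markers.json)")
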