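# Stage 2: mesh both cavity surfaces and run the constant-inflow transient
# on each. Writes VTU volume meshes, probe time-series CSVs, and the runs.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(), value = TRUE))), "00_common.R"))

out <- out_dir()
geo <- need_stage(out, "01_geometries.rds", "01_generate_geometries.R")

max_cell_volume <- as.numeric(cli_arg("--max-cell-volume", "1.1e-8"))
near_wall <- as.numeric(cli_arg("--near-wall-refinement", "2"))
cfg <- solver_config(max_time = as.numeric(cli_arg("--max-time", "0.12")))
props <- fluid_properties()
inflow <- function(t) constant_inflow(t)
outlet <- outlet_model()

simulate <- function(surface, label) {
  message(label, ": meshing")
  mesh <- tetrahedralize(surface, max_cell_volume,
                         near_wall_refinement = near_wall, jitter = 0)
  message(label, ": ", nrow(mesh$cells), " cells, solving to ",
          cfg$max_time, " s")
  fem <- build_fem(mesh$vertices, mesh$cells)
  prob <- setup_solver(fem, props, cfg, flow_bcs(mesh, inflow, outlet, props))
  run <- solve_transient(prob, probes = tube_probes(mesh, fem))
  write_mesh(mesh, stage_path(out, paste0(label, ".vtu")))
  write_series_csv(run, stage_path(out, paste0(label, "_series.csv")))
  list(mesh = mesh, run = run)
}

cases <- list(smoothed = simulate(geo$smoothed, "smoothed"),
              detailed = simulate(geo$detailed, "detailed"))
saveRDS(list(cases = cases, cfg = cfg, props = props,
             max_cell_volume = max_cell_volume, near_wall = near_wall),
        stage_path(out, "02_runs.rds"))
message("wrote ", out, "/02_runs.rds (+ VTU meshes, series CSVs)")
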