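test_that("rest is a fixed point and steps conserve the divergence invariant", {
  g <- rect_grid2d(12, 12, 2 * pi, 2 * pi)
  fem <- build_fem(g$vertices, g$cells, periodic_fold2d(g))
  props <- fluid_properties(density = 1, dynamic_viscosity = 0.05)
  cfg <- solver_config("EMAC", max_time = 0.2, output_interval = 0.1)
  prob <- setup_solver(fem, props, cfg, flow_bcs_spec())
  s0 <- flow_state(matrix(0, fem$nv, 2))
  s1 <- step_flow(prob, s0, 0.01)
  expect_equal(max(abs(s1$u)), 0)
  run <- solve_transient(prob, state0 = flow_state(taylor_green(fem$vertices)))
  expect_true(all(run$series$div_rel <= cfg$projection_tolerance))
  expect_lt(kinetic_energy(fem, run$snapshots[[length(run$snapshots)]]$u),
            kinetic_energy(fem, run$snapshots[[1]]$u))
})

test_that("Darcy drag equals -(nu/k) m u on fully porous cells and is implicit-stable", {
  g <- rect_grid2d(6, 6, 1, 1)
  fem <- build_fem(g$vertices, g$cells, periodic_fold2d(g))
  spec <- porous_layer_spec(thickness = 0.01, sigma = 20)
  props <- fluid_properties()
  u <- cbind(sin(fem$vertices[, 1]), cos(fem$vertices[, 2]))
  fd <- darcy_drag(fem, u, seq_len(fem$nc), spec, props)
  c_exp <- props$kinematic_viscosity / spec$permeability
  expect_equal(fd, -c_exp * (fem$m * u))
  # one large explicit-unstable step stays bounded through the implicit split
  cfg <- solver_config(max_time = 1, output_interval = 1)
  prob <- setup_solver(fem, fluid_properties(density = 1, dynamic_viscosity = 0.1),
                       cfg, flow_bcs_spec(),
                       porous = list(cells = seq_len(fem$nc), spec = spec))
  st <- step_flow(prob, flow_state(u), 1)
  expect_true(all(is.finite(st$u)))
  expect_lt(max(abs(st$u)), max(abs(u)))
})

test_that("time-step estimate scales with the mesh and velocity", {
  fem <- fx_fem()
  prob <- setup_solver(fem, fluid_properties(),
                       solver_config(max_time = 0.1),
                       flow_bcs(fx_mesh(), function(t) constant_inflow(t)))
  dt0 <- estimate_timestep(prob, matrix(0, fem$nv, 3))
  u1 <- matrix(1, fem$nv, 3)
  dt1 <- estimate_timestep(prob, u1)
  expect_gt(dt0, 0)
  expect_gt(dt0, dt1)  # advection limit tightens the viscous-only bound
  dt2 <- estimate_timestep(prob, 2 * u1)
  expect_gt(dt1, dt2)
})

test_that("configuration and boundary validation fail loudly", {
  expect_error(solver_config(cfl_safety = 0), class = "ventriflow_validation_error")
  expect_error(solver_config("UPWIND"))
  expect_error(porous_layer_spec(0.01, -1), class = "ventriflow_validation_error")
  # a mesh whose tubes are unresolvable must be rejected by flow_bcs
  surf <- build_smoothed_cavity(cavity_params())
  coarse <- tetrahedralize(surf, max_cell_volume = (0.02)^3 / 6, jitter = 0)
  expect_error(flow_bcs(coarse, function(t) constant_inflow(t)),
               "too coarse")
})
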