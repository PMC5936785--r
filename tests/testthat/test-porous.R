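test_that("porosity / conductivity / permeability conversions are exact inverses", {
  props <- fluid_properties()
  expect_identical(sigma_from_conductivity(5e-4), 7)
  expect_equal(sigma_from_conductivity(1.75e-4), 20)
  expect_equal(sigma_from_conductivity(1e-3), 3.5)   # K doubled -> sigma halved
  k7 <- permeability_from_sigma(7)
  expect_equal(k7, props$dynamic_viscosity^2 / (7 * props$density * props$gravity))
  expect_equal(sigma_from_conductivity(conductivity_from_permeability(k7)), 7,
               tolerance = 1e-12)
  expect_gt(permeability_from_sigma(7), permeability_from_sigma(70))
  expect_error(sigma_from_conductivity(0), class = "ventriflow_validation_error")
  expect_error(permeability_from_sigma(-1), class = "ventriflow_validation_error")
})

test_that("porous_layer_spec links thickness, sigma, K and k consistently", {
  spec <- porous_layer_spec(0.012, 20)
  expect_equal(spec$hydraulic_conductivity, 0.0035 / 20)
  expect_equal(spec$permeability, permeability_from_sigma(20))
  expect_output(print(spec), "porous_layer_spec")
})

test_that("porous layer cells hug the cavity wall and grow with thickness", {
  mesh <- fx_mesh()
  thin <- porous_layer_cells(mesh, 0.004)
  thick <- porous_layer_cells(mesh, 0.010)
  expect_gt(length(thin), 0)
  expect_lt(length(thin), nrow(mesh$cells))
  expect_true(all(thin %in% thick))
  expect_gt(length(thick), length(thin))
  # selected centroids stay below the basal plane (tubes are excluded)
  bp <- attr(mesh, "base_plane")
  hc <- as.vector(sweep(cell_centroids(mesh), 2, bp$point) %*% bp$normal)
  expect_true(all(hc[thick] < 0))
})

test_that("surrogate error is signed, relative, and NA-safe", {
  mk <- function(dp, wss, vs) list(delta_p = dp, wss_median = wss,
                                   total_vortex_surface = vs)
  ref <- mk(4.9, 0.39, 0.0484)
  expect_equal(surrogate_error(ref, ref), c(delta_p = 0, wss_median = 0,
                                            total_vortex_surface = 0))
  e <- surrogate_error(mk(2.6, 0.36, 0.0546), ref)
  expect_equal(unname(e["delta_p"]), (4.9 - 2.6) / 4.9)
  expect_equal(unname(e["wss_median"]), (0.39 - 0.36) / 0.39)
  expect_lt(e["total_vortex_surface"], 0)  # overshoot reported negative
  ez <- surrogate_error(mk(1, 1, 1), mk(0, 1, 1))
  expect_true(is.na(ez["delta_p"]))
})
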