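test_that("smoothed cavity is a watertight labelled surface with exact tubes", {
  surf <- fx_surface()
  chk <- surface_check(surf)
  expect_true(chk$watertight)
  expect_true(chk$oriented)
  expect_identical(euler_characteristic(surf), 2L)
  expect_setequal(unique(surf$face_labels),
                  c("wall", "inlet_cap", "outlet_cap"))
  ti <- attr(surf, "tube_info")
  expect_equal(ti$inlet$length, 0.050)
  expect_equal(ti$outlet$length, 0.070)
  # cap faces are planar and perpendicular to the tube axis: every inlet-cap
  # vertex projects to the same axial coordinate (up to extraction tolerance)
  for (side in c("inlet_cap", "outlet_cap")) {
    tb <- if (side == "inlet_cap") ti$inlet else ti$outlet
    vv <- surf$vertices[unique(as.vector(
      surf$faces[surf$face_labels == side, , drop = FALSE])), , drop = FALSE]
    ax <- as.vector(sweep(vv, 2, tb$valve_center) %*% (tb$axis / sqrt(sum(tb$axis^2))))
    expect_lt(diff(range(ax)), 1e-9)
    expect_equal(mean(ax), tb$length, tolerance = 1e-6)
  }
})

test_that("half-ellipsoid volume matches the closed form with tubes disabled", {
  p <- cavity_params(inlet_radius = 0, outlet_radius = 0)
  surf <- build_smoothed_cavity(p)
  vol <- enclosed_volume(surf)
  exact <- (2 / 3) * pi * p$long_axis_length * p$base_radius^2
  expect_lt(abs(vol / exact - 1), 0.01)
})

test_that("trabeculation is deterministic and the zero case is the identity", {
  surf <- fx_surface()
  expect_identical(add_trabeculation(surf, trabeculation_params(amplitude = 0)),
                   surf)
  t1 <- add_trabeculation(surf, trabeculation_params(seed = 7L))
  t2 <- add_trabeculation(surf, trabeculation_params(seed = 7L))
  expect_identical(t1$vertices, t2$vertices)
  t3 <- add_trabeculation(surf, trabeculation_params(seed = 8L))
  expect_false(identical(t1$vertices, t3$vertices))
  # protrusions only move wall vertices
  cap_nodes <- unique(as.vector(
    surf$faces[surf$face_labels != "wall", , drop = FALSE]))
  expect_identical(t1$vertices[cap_nodes, ], surf$vertices[cap_nodes, ])
})

test_that("volume-fraction calibration lands in the hull-measured band", {
  surf <- fx_surface()
  det <- add_trabeculation(surf,
                           trabeculation_params(target_volume_fraction = 0.3,
                                                seed = 3L))
  m_s <- compute_markers(surf)
  m_d <- compute_markers(det)
  expect_lt(m_s$trabecular_volume_pct, 2)
  expect_gt(m_d$trabecular_volume_pct, 15)
  expect_lt(m_d$trabecular_volume_pct, 27)
  # markers of the pair agree on everything the trabeculae do not touch
  expect_equal(m_d$inlet_area, m_s$inlet_area)
  expect_equal(m_d$alpha, m_s$alpha)
  expect_equal(m_d$d, m_s$d)
  expect_gt(m_s$alpha, 0)
  expect_lt(m_s$alpha, 180)
})

test_that("invalid cavity parameters raise named geometry errors", {
  expect_error(cavity_params(inlet_offset = c(0, 0), outlet_offset = c(0.001, 0)),
               "overlap", class = "ventriflow_geometry_error")
  expect_error(cavity_params(inlet_radius = 0.0175),
               "basal disc", class = "ventriflow_geometry_error")
  expect_error(trabeculation_params(target_volume_fraction = 0.6),
               class = "ventriflow_validation_error")
})
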