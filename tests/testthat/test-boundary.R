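test_that("E-A wave has two raised-cosine lobes separated by diastasis", {
  p <- ea_wave_params()
  expect_equal(ea_wave(p$tp_E, p), p$A_E)       # E peak
  expect_equal(ea_wave(p$tp_A, p), p$A_A)       # A peak
  expect_equal(ea_wave(c(p$t0_E, p$t1_E, p$t0_A, p$t1_A), p), rep(0, 4))
  expect_equal(ea_wave(c(0.30, 0.40, -0.1, 0.7), p), rep(0, 4))  # diastasis/outside
  expect_true(all(ea_wave(seq(-0.1, 0.8, by = 1e-3), p) >= 0))
  expect_error(ea_wave_params(t0_A = 0.2),
               class = "ventriflow_validation_error")
})

test_that("constant inflow ramps linearly to its plateau", {
  expect_equal(constant_inflow(c(-1, 0, 0.01, 0.02, 5)),
               c(0, 0, 0.275, 0.55, 0.55))
  expect_equal(constant_inflow(c(0, 1), speed = 2, ramp = 0), c(2, 2))
})

test_that("resistive outlet model and stroke volume match closed forms", {
  expect_equal(outlet_pressure(0), 10700)
  expect_equal(outlet_pressure(2e-4), 10700 + 5e6 * 2e-4)
  m <- outlet_model(baseline_pressure = 100, resistance = 10)
  expect_equal(outlet_pressure(c(0, 1), m), c(100, 110))
  # raised-cosine lobe integral is (A/2) * lobe duration
  p <- ea_wave_params()
  area <- 6e-4
  exact <- area * ((p$A_E / 2) * (p$t1_E - p$t0_E) +
                     (p$A_A / 2) * (p$t1_A - p$t0_A))
  expect_equal(stroke_volume(p, area), exact, tolerance = 1e-8)
})
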