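# Inflow waveforms (constant and synthetic E-A wave) and the resistive
# outlet pressure model.

#' Parameters of the synthetic E-A transmitral inflow wave
#'
#' Two raised-cosine lobes (early-filling E wave and atrial-contraction A
#' wave) separated by a diastasis of zero inflow. With the peak at the
#' interval midpoint (the default) each lobe starts and ends at exactly zero.
#'
#' @param A_E,A_A peak velocities of the E and A lobes, m/s
#' @param t0_E,t1_E start/end of the E lobe, s
#' @param t0_A,t1_A start/end of the A lobe, s
#' @param tp_E,tp_A peak times (default: interval midpoints), s
#' @return validated `ea_wave_params`
#' @export
ea_wave_params <- function(A_E = 0.55, A_A = 0.35,
                           t0_E = 0, t1_E = 0.25,
                           t0_A = 0.45, t1_A = 0.60,
                           tp_E = (t0_E + t1_E) / 2,
                           tp_A = (t0_A + t1_A) / 2) {
  check_number(A_E, "A_E", 0)
  check_number(A_A, "A_A", 0)
  for (nm in c("t0_E", "t1_E", "t0_A", "t1_A", "tp_E", "tp_A"))
    check_number(get(nm), nm)
  if (!(t0_E < tp_E && tp_E < t1_E && t1_E <= t0_A && t0_A < tp_A && tp_A < t1_A))
    stop_vf("E-A wave times must satisfy t0_E < tp_E < t1_E <= t0_A < tp_A ",
            "< t1_A", class = "ventriflow_validation_error")
  structure(list(A_E = A_E, A_A = A_A, t0_E = t0_E, t1_E = t1_E,
                 tp_E = tp_E, t0_A = t0_A, t1_A = t1_A, tp_A = tp_A),
            class = "ea_wave_params")
}

#' Synthetic E-A wave inflow velocity
#'
#' Piecewise raised cosines: `(A/2)(1 + cos(2 pi (t - tp)/(t1 - t0)))` inside
#' each lobe, zero in the diastasis and outside both lobes.
#'
#' @param t time, s (vectorized)
#' @param params `ea_wave_params`
#' @return inflow velocity, m/s
#' @export
ea_wave <- function(t, params = ea_wave_params()) {
  stopifnot(inherits(params, "ea_wave_params"))
  v <- numeric(length(t))
  inE <- t >= params$t0_E & t <= params$t1_E
  v[inE] <- (params$A_E / 2) *
    (1 + cos(2 * pi * (t[inE] - params$tp_E) / (params$t1_E - params$t0_E)))
  inA <- t >= params$t0_A & t <= params$t1_A
  v[inA] <- (params$A_A / 2) *
    (1 + cos(2 * pi * (t[inA] - params$tp_A) / (params$t1_A - params$t0_A)))
  pmax(v, 0)
}

#' Constant flat-profile inflow velocity with a start-up ramp
#'
#' @param t time, s (vectorized)
#' @param speed plateau inflow speed, m/s (default 0.55)
#' @param ramp linear start-up interval, s (0 disables the ramp)
#' @return inflow velocity, m/s
#' @export
constant_inflow <- function(t, speed = 0.55, ramp = 0.02) {
  check_number(speed, "speed", 0)
  check_number(ramp, "ramp", 0)
  if (ramp == 0) return(rep(speed, length(t)))
  speed * pmin(pmax(t / ramp, 0), 1)
}

#' Resistive outlet pressure model
#'
#' @param baseline_pressure Pa (default 10700, a normal end-diastolic
#'   arterial pressure of 80 mmHg)
#' @param resistance Pa s/m^3 (default 5e6: outlet pressure rises by about
#'   1 kPa at a peak systolic flow of 2e-4 m^3/s)
#' @return `outlet_model`
#' @export
outlet_model <- function(baseline_pressure = 10700, resistance = 5e6) {
  check_number(baseline_pressure, "baseline_pressure", 0)
  check_number(resistance, "resistance", 0)
  structure(list(baseline_pressure = baseline_pressure,
                 resistance = resistance), class = "outlet_model")
}

#' Outlet pressure for a given instantaneous flow rate
#'
#' @param flow_rate m^3/s (vectorized)
#' @param model `outlet_model`
#' @return pressure, Pa
#' @export
outlet_pressure <- function(flow_rate, model = outlet_model()) {
  stopifnot(inherits(model, "outlet_model"))
  model$baseline_pressure + model$resistance * flow_rate
}

#' Stroke volume of an E-A wave through an inlet orifice
#'
#' Integrates `ea_wave(t) * inlet_area` over `[t0_E, t1_A]` by composite
#' Simpson quadrature.
#'
#' @param params `ea_wave_params`
#' @param inlet_area m^2
#' @param n quadrature intervals (even; default 2000)
#' @return volume, m^3
#' @export
stroke_volume <- function(params, inlet_area, n = 2000) {
  stopifnot(inherits(params, "ea_wave_params"))
  check_number(inlet_area, "inlet_area", 0)
  n <- 2L * ceiling(n / 2)
  t <- seq(params$t0_E, params$t1_A, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  hq <- (params$t1_A - params$t0_E) / n
  sum(w * ea_wave(t, params)) * hq / 3 * inlet_area
}
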