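# Porous-layer trabeculation surrogate: porosity/conductivity/permeability
# conversions, the near-wall layer cell selection, the thickness x porosity
# sensitivity sweep, and surrogate scoring against a detailed reference.

#' Porosity parameter from hydraulic conductivity
#'
#' `sigma = mu / K`, kg/m^2.
#'
#' @param conductivity hydraulic conductivity K, m/s
#' @param props `fluid_properties`
#' @return sigma, kg/m^2
#' @export
sigma_from_conductivity <- function(conductivity, props = fluid_properties()) {
  check_number(conductivity, "conductivity", 0, strict_lower = TRUE)
  props$dynamic_viscosity / conductivity
}

#' Intrinsic permeability from the porosity parameter
#'
#' `k = mu^2 / (sigma rho g)`, m^2 (via `K = mu / sigma` and
#' `k = K mu / (rho g)`).
#'
#' @param sigma porosity parameter, kg/m^2
#' @param props `fluid_properties`
#' @return permeability, m^2
#' @export
permeability_from_sigma <- function(sigma, props = fluid_properties()) {
  check_number(sigma, "sigma", 0, strict_lower = TRUE)
  props$dynamic_viscosity^2 / (sigma * props$density * props$gravity)
}

#' Hydraulic conductivity from intrinsic permeability
#'
#' `K = k rho g / mu`, m/s; exact algebraic inverse of the sigma/K/k chain.
#'
#' @param permeability intrinsic permeability k, m^2
#' @param props `fluid_properties`
#' @return conductivity, m/s
#' @export
conductivity_from_permeability <- function(permeability,
                                           props = fluid_properties()) {
  check_number(permeability, "permeability", 0, strict_lower = TRUE)
  permeability * props$density * props$gravity / props$dynamic_viscosity
}

#' Porous layer specification
#'
#' Holds the layer thickness and the exactly linked resistance parameters:
#' `sigma = mu / K` and `k = K mu / (rho g)`.
#'
#' @param thickness layer thickness, m
#' @param sigma porosity parameter, kg/m^2
#' @param props `fluid_properties` fixing mu, rho, g in the conversions
#' @return `porous_layer_spec` with `thickness`, `sigma`,
#'   `hydraulic_conductivity` (m/s), `permeability` (m^2)
#' @export
porous_layer_spec <- function(thickness, sigma, props = fluid_properties()) {
  check_number(thickness, "thickness", 0, strict_lower = TRUE)
  check_number(sigma, "sigma", 0, strict_lower = TRUE)
  structure(list(thickness = thickness, sigma = sigma,
                 hydraulic_conductivity = props$dynamic_viscosity / sigma,
                 permeability = permeability_from_sigma(sigma, props)),
            class = "porous_layer_spec")
}

#' @export
print.porous_layer_spec <- function(x, ...) {
  cat("porous_layer_spec: thickness", x$thickness, "m  sigma", x$sigma,
      "kg/m^2  K", signif(x$hydraulic_conductivity, 4), "m/s  k",
      signif(x$permeability, 4), "m^2\n")
  invisible(x)
}

#' Cells of the near-wall porous layer
#'
#' Cells whose centroid lies within `thickness` of the cavity wall, via
#' [tag_porous_layer()] (exact point-to-triangle distances; tube cells above
#' the base plane are never selected when that metadata is present). A basal
#' standoff band just below the valve plane is also excluded: the layer is a
#' trabeculation surrogate, and trabeculae do not reach the smooth fibrous
#' valve region -- the paired trabeculation generator fades its displacement
#' to zero over the same band, so the surrogate occupies exactly the region
#' its target occupies.
#'
#' @param mesh `volume_mesh` with wall tags
#' @param thickness layer thickness, m
#' @param basal_standoff_frac height of the excluded basal band as a
#'   fraction of the cavity depth (default 0.12, matching the trabeculation
#'   taper; 0 disables). Ignored when the mesh carries no base-plane
#'   metadata.
#' @return integer cell indices
#' @export
porous_layer_cells <- function(mesh, thickness, basal_standoff_frac = 0.12) {
  check_number(thickness, "thickness", 0, strict_lower = TRUE)
  check_number(basal_standoff_frac, "basal_standoff_frac", 0, 1)
  sel <- tag_porous_layer(mesh, thickness)$cell_region == "porous"
  bp <- attr(mesh, "base_plane")
  if (!is.null(bp) && basal_standoff_frac > 0) {
    hc <- as.vector(sweep(cell_centroids(mesh), 2, bp$point) %*% bp$normal)
    sel <- sel & hc < basal_standoff_frac * min(hc)
  }
  which(sel)
}

#' Thickness x porosity sensitivity sweep of the porous surrogate
#'
#' Runs one transient simulation per (thickness, sigma) grid point on the
#' given (smoothed) mesh with the porous layer installed, and summarizes each
#' run. Solver failures at individual grid points are caught and flagged
#' without aborting the sweep.
#'
#' @param mesh smoothed-cavity `volume_mesh`
#' @param thicknesses layer thicknesses, m (non-empty)
#' @param sigmas porosity parameters, kg/m^2 (non-empty)
#' @param inflow `function(t)` inflow speed, m/s
#' @param q_threshold Q-criterion threshold for the vortex surface, 1/s^2
#' @param props `fluid_properties`
#' @param cfg `solver_config`
#' @param outlet `outlet_model`
#' @param window_frames pressure-drop averaging window, saved frames
#' @return `sweep_result`: `grid` data frame (thickness, sigma, failed,
#'   delta_p, wss_median, total_vortex_surface), `summaries` list (NULL where
#'   failed), `errors` character vector of failure messages
#' @export
run_sweep <- function(mesh, thicknesses, sigmas, inflow,
                      q_threshold, props = fluid_properties(),
                      cfg = solver_config(), outlet = outlet_model(),
                      window_frames = 10) {
  if (!length(thicknesses) || !length(sigmas))
    stop_vf("thicknesses and sigmas must be non-empty",
            class = "ventriflow_validation_error")
  grid <- expand.grid(thickness = as.numeric(thicknesses),
                      sigma = as.numeric(sigmas), KEEP.OUT.ATTRS = FALSE)
  fem <- build_fem(mesh$vertices, mesh$cells)
  probes <- tube_probes(mesh, fem)
  summaries <- vector("list", nrow(grid))
  errors <- rep(NA_character_, nrow(grid))
  cols <- matrix(NA_real_, nrow(grid), 3)
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      spec <- porous_layer_spec(grid$thickness[i], grid$sigma[i], props)
      cells <- porous_layer_cells(mesh, spec$thickness)
      bcs <- flow_bcs(mesh, inflow, outlet, props)
      prob <- setup_solver(fem, props, cfg, bcs,
                           porous = list(cells = cells, spec = spec))
      run <- solve_transient(prob, probes = probes)
      summarize_run(run, fem, mesh, q_threshold, props, window_frames)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      summaries[[i]] <- res
      cols[i, ] <- c(res$delta_p, res$wss_median, res$total_vortex_surface)
    }
  }
  grid$failed <- !is.na(errors)
  grid$delta_p <- cols[, 1]
  grid$wss_median <- cols[, 2]
  grid$total_vortex_surface <- cols[, 3]
  structure(list(grid = grid, summaries = summaries, errors = errors),
            class = "sweep_result")
}

#' Relative surrogate errors versus a detailed-geometry reference
#'
#' For each of the pressure drop, WSS median and total vortex surface:
#' `(x_detailed - x) / x_detailed` — magnitude is the usual relative error,
#' and the sign is negative exactly when the surrogate overshoots the
#' detailed value. A zero reference yields `NA` (undefined), not infinity.
#'
#' @param summary `hemodynamic_summary` of the surrogate (or smoothed) run
#' @param detailed `hemodynamic_summary` of the detailed reference run
#' @return named numeric vector: `delta_p`, `wss_median`,
#'   `total_vortex_surface`
#' @export
surrogate_error <- function(summary, detailed) {
  err1 <- function(x, ref) if (!is.finite(ref) || ref == 0) NA_real_
    else (ref - x) / ref
  c(delta_p = err1(summary$delta_p, detailed$delta_p),
    wss_median = err1(summary$wss_median, detailed$wss_median),
    total_vortex_surface = err1(summary$total_vortex_surface,
                                detailed$total_vortex_surface))
}
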