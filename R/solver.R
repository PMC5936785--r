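# Incompressible Navier-Stokes solver: explicit SSP Runge-Kutta momentum
# advance (EMAC or CONV nonlinear form, exact P1 quadrature), implicit
# diagonal Darcy drag, and a non-incremental fractional-step pressure
# projection on the compatible lumped-mass Laplacian. The projection system
# depends only on the mesh and boundary sets, so its Cholesky factor is
# computed once per problem and reused every step.

#' Solver configuration
#'
#' @param nonlinear_form `"EMAC"` (energy, momentum and angular-momentum
#'   conserving) or `"CONV"` (convective `u . grad u`)
#' @param cfl_safety CFL safety factor in (0, 1]
#' @param rk_stages explicit Runge-Kutta stages (2 or 3; default 3)
#' @param projection_tolerance relative weak-divergence tolerance verified
#'   after each projection
#' @param max_time simulated duration, s
#' @param output_interval snapshot spacing, s
#' @param stabilization pressure-stabilization weight in (0, 1): the
#'   projection operator is `(1 - a) A + a L` with `A` the compatible
#'   lumped-mass Poisson operator and `L` the Galerkin stiffness, which
#'   bounds the response of the pressure modes the equal-order pair cannot
#'   control
#' @param seed unused (the solver is deterministic); kept for config-file
#'   compatibility
#' @return `solver_config`
#' @export
solver_config <- function(nonlinear_form = c("EMAC", "CONV"), cfl_safety = 0.5,
                          rk_stages = 3L, projection_tolerance = 1e-6,
                          max_time = 0.35, output_interval = 0.005,
                          stabilization = 0.05, seed = NULL) {
  nonlinear_form <- match.arg(nonlinear_form)
  check_number(cfl_safety, "cfl_safety", 0, 1, strict_lower = TRUE)
  if (!rk_stages %in% c(2L, 3L))
    stop_vf("rk_stages must be 2 or 3", class = "ventriflow_validation_error")
  check_number(projection_tolerance, "projection_tolerance", 0, strict_lower = TRUE)
  check_number(max_time, "max_time", 0)
  check_number(output_interval, "output_interval", 0, strict_lower = TRUE)
  check_number(stabilization, "stabilization", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(nonlinear_form = nonlinear_form, cfl_safety = cfl_safety,
                 rk_stages = as.integer(rk_stages),
                 projection_tolerance = projection_tolerance,
                 max_time = max_time, output_interval = output_interval,
                 stabilization = stabilization, seed = seed),
            class = "solver_config")
}

#' Flow state: nodal velocity and kinematic pressure at one instant
#'
#' @param u nodal velocity (nv x d), m/s
#' @param p nodal kinematic pressure, m^2/s^2 (physical pressure = rho p)
#' @param time s
#' @return `flow_state`
#' @export
flow_state <- function(u, p = numeric(nrow(u)), time = 0) {
  structure(list(u = as.matrix(u), p = as.numeric(p), time = time),
            class = "flow_state")
}

#' Boundary conditions of a flow problem
#'
#' @param dirichlet list of `list(nodes, value)` velocity conditions; `value`
#'   is `function(t)` returning either a length-d vector or an
#'   `length(nodes) x d` matrix. Later entries override earlier ones on
#'   shared nodes.
#' @param pressure_nodes optional pressure-Dirichlet dof indices; normally
#'   empty. With `outlet_faces` the outlet pressure acts weakly through the
#'   boundary traction term; without either, the domain is enclosed/periodic
#'   and the first dof is pinned to zero
#' @param pressure_value `function(t, q_out)` kinematic outlet pressure
#' @param outlet_faces face matrix (rows of dof triples) over which the
#'   outlet pressure traction, outlet flux and backflow penalty act
#' @param body_force per-unit-mass force, length d
#' @return `flow_bcs` list
#' @export
flow_bcs_spec <- function(dirichlet = list(), pressure_nodes = integer(0),
                          pressure_value = function(t, q_out) 0,
                          outlet_faces = NULL, body_force = NULL) {
  structure(list(dirichlet = dirichlet, pressure_nodes = pressure_nodes,
                 pressure_value = pressure_value, outlet_faces = outlet_faces,
                 body_force = body_force), class = "flow_bcs")
}

#' Boundary conditions for a labelled ventricle-like volume mesh
#'
#' No-slip on wall nodes, a flat inflow profile along the inlet tube axis on
#' the inlet cap, and a flux-matched flat outflow profile along the outlet
#' tube axis: with rigid walls an incompressible flow must discharge the
#' instantaneous inflow exactly, so the outflow speed is the inflow speed
#' scaled by the discrete flux ratio of the two plugs. No-slip wins on the
#' cap rims (nodes shared with the wall), which makes the interpolated
#' velocity vanish on every wall face; the total boundary flux then reduces
#' to the two cap-face integrals and the flux matching equates them to
#' round-off at every instant. The resistive outlet model gauges the
#' (otherwise level-free) pressure field so that the outlet cap sits at its
#' predicted pressure.
#'
#' @param mesh `volume_mesh` with inlet/outlet/wall tags (and `tube_info`)
#' @param inflow `function(t)` inflow speed, m/s
#' @param outlet `outlet_model`
#' @param props `fluid_properties`
#' @return `flow_bcs`
#' @export
flow_bcs <- function(mesh, inflow, outlet = outlet_model(),
                     props = fluid_properties()) {
  tags <- mesh$boundary_tags
  for (need in c("inlet", "outlet", "wall"))
    if (!any(tags == need))
      stop_vf("mesh lacks ", need, "-tagged boundary faces",
              class = "ventriflow_validation_error")
  wall_nodes <- unique(as.vector(mesh$boundary_faces[tags == "wall", ]))
  inlet_nodes <- unique(as.vector(mesh$boundary_faces[tags == "inlet", ]))
  outlet_nodes <- unique(as.vector(mesh$boundary_faces[tags == "outlet", ]))
  ti <- attr(mesh, "tube_info")
  tube_dir <- function(which_tag, tube) {
    if (!is.null(tube)) return(unit(tube$axis))
    fl <- mesh$boundary_faces[tags == which_tag, , drop = FALSE]
    v0 <- mesh$vertices[fl[, 1], , drop = FALSE]
    nrm <- cross3(mesh$vertices[fl[, 2], , drop = FALSE] - v0,
                  mesh$vertices[fl[, 3], , drop = FALSE] - v0)
    unit(colSums(nrm))
  }
  dir_in <- -tube_dir("inlet", ti$inlet)    # into the cavity
  dir_out <- tube_dir("outlet", ti$outlet)  # out of the cavity
  # no-slip at the rims: only cap nodes not touching any wall face carry
  # the plug, so the interpolated field is zero on all wall faces
  inlet_core <- setdiff(inlet_nodes, wall_nodes)
  outlet_core <- setdiff(outlet_nodes, wall_nodes)
  if (!length(inlet_core) || !length(outlet_core))
    stop_vf("inlet/outlet cap has no interior nodes (mesh too coarse for ",
            "the tube radius)", class = "ventriflow_validation_error")
  # discrete flux of a unit plug on a node set over the boundary faces
  # (rim-straddling faces contribute partially)
  bf <- mesh$boundary_faces
  v0 <- mesh$vertices[bf[, 1], , drop = FALSE]
  Nf <- cross3(mesh$vertices[bf[, 2], , drop = FALSE] - v0,
               mesh$vertices[bf[, 3], , drop = FALSE] - v0) / 2
  plug_flux <- function(nodes, dir) {
    ind <- numeric(nrow(mesh$vertices))
    ind[nodes] <- 1
    cov <- (ind[bf[, 1]] + ind[bf[, 2]] + ind[bf[, 3]]) / 3
    sum(cov * as.vector(Nf %*% dir))
  }
  flux_ratio <- -plug_flux(inlet_core, dir_in) /
    plug_flux(outlet_core, dir_out)
  rho <- props$density
  flow_bcs_spec(
    dirichlet = list(
      list(nodes = wall_nodes, value = function(t) c(0, 0, 0)),
      list(nodes = inlet_core, value = function(t) dir_in * inflow(t)),
      list(nodes = outlet_core,
           value = function(t) dir_out * (flux_ratio * inflow(t)))),
    pressure_value = function(t, q_out) outlet_pressure(q_out, outlet) / rho,
    outlet_faces = mesh$boundary_faces[tags == "outlet", , drop = FALSE],
    body_force = props$body_force)
}

#' Set up a flow problem (operators, boundary sets, projection factorization)
#'
#' @param fem `fem_structure` (or a `volume_mesh`, converted internally)
#' @param props `fluid_properties`
#' @param cfg `solver_config`
#' @param bcs `flow_bcs`
#' @param porous optional `list(cells, spec)`: porous cell indices and a
#'   `porous_layer_spec` providing the permeability
#' @return `flow_problem`
#' @export
setup_solver <- function(fem, props, cfg, bcs, porous = NULL) {
  if (inherits(fem, "volume_mesh")) {
    mesh <- fem
    fem <- build_fem(mesh$vertices, mesh$cells)
    if (is.null(porous) && any(mesh$cell_region == "porous"))
      stop_vf("mesh has porous cells but no porous spec was given; pass ",
              "porous = list(cells, spec)")
  }
  d <- fem$d
  # velocity Dirichlet: later entries override earlier ones
  dir_nodes <- integer(0)
  for (bc in bcs$dirichlet) dir_nodes <- union(dir_nodes, bc$nodes)
  maskV <- rep(1, fem$nv)
  maskV[dir_nodes] <- 0
  pnodes <- bcs$pressure_nodes
  has_outlet <- !is.null(bcs$outlet_faces) && nrow(bcs$outlet_faces) > 0
  # with a weak (traction) outlet the boundary integral of the constant
  # pressure mode acts on the free cap velocities, so the operator is
  # definite without any pinned value; domains whose boundary velocities are
  # fully prescribed (enclosed, periodic, or flux-matched outflow) pin one
  # node to fix the level
  free_cap <- has_outlet &&
    any(maskV[unique(as.vector(bcs$outlet_faces))] > 0)
  pinned <- FALSE
  if (!length(pnodes) && !free_cap) {
    pnodes <- 1L
    pinned <- TRUE
  }
  pfree <- setdiff(seq_len(fem$nv), pnodes)

  A <- NULL
  w <- maskV / fem$m
  for (k in seq_len(d)) {
    Ak <- fem$B[[k]] %*% (w * Matrix::t(fem$B[[k]]))
    A <- if (is.null(A)) Ak else A + Ak
  }
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  # pressure nodes whose whole velocity stencil is Dirichlet have a zero
  # row/column of A: their divergence is fixed by the boundary data and the
  # pressure there moves nothing, so they leave the constraint set
  dA <- Matrix::diag(A)
  pfree <- pfree[dA[pfree] > 1e-12 * mean(dA)]
  A_ff <- A[pfree, pfree, drop = FALSE]
  # The compatible operator A is near-singular on pressure modes the
  # equal-order pair cannot control (checkerboards, cap-adjacent layers):
  # the classical inf-sup fragility. The projection therefore solves with
  # the stabilized operator S = (1-a) A + a L, L the Galerkin pressure
  # stiffness (A <= L in quadratic form). The velocity-correction operator
  # built on S has eigenvalues t/((1-a) t + a) <= 1 over the pencil
  # spectrum t in [0, 1], so every step is non-expansive in the lumped
  # energy norm, while ill modes (t ~ 0) move the velocity by only O(t/a)
  # instead of the unbounded exact-compatible response. Refinement toward A
  # in step_flow() then recovers the exact compatible projection on the
  # well-conditioned modes.
  alpha <- cfg$stabilization
  L_ff <- fem$L[pfree, pfree, drop = FALSE]
  S_ff <- (1 - alpha) * A_ff + alpha * L_ff
  chol_S <- Matrix::Cholesky(Matrix::forceSymmetric(S_ff), LDL = FALSE,
                             perm = TRUE)
  # outlet face geometry for flux and backflow penalty
  of <- bcs$outlet_faces
  out_geo <- NULL
  svec <- NULL
  bsv <- NULL
  if (!is.null(of) && nrow(of)) {
    v0 <- fem$vertices[of[, 1], , drop = FALSE]
    nrm <- cross3(fem$vertices[of[, 2], , drop = FALSE] - v0,
                  fem$vertices[of[, 3], , drop = FALSE] - v0) / 2
    out_geo <- list(faces = of, normal = nrm, area = row_norms(nrm),
                    unit_n = normalize_rows(nrm))
    # outlet surface term of the weak pressure gradient, int_out phi_j n_k:
    # the nodal correction B' p alone equals the true pressure force plus
    # this term, so it is subtracted (with the prescribed outlet pressure)
    # to impose the pressure value in the weak sense; without it a constant
    # ambient pressure would blow fluid out through the open cap
    svec <- matrix(0, fem$nv, d)
    for (l in 1:3) for (k in seq_len(d))
      svec[, k] <- svec[, k] + scatter_add(of[, l], nrm[, k] / 3, fem$nv)
    bsv <- numeric(fem$nv)
    for (k in seq_len(d))
      bsv <- bsv + as.vector(fem$B[[k]] %*% (w * svec[, k]))
  }
  cdrag <- numeric(fem$nv)
  if (!is.null(porous) && length(porous$cells)) {
    k_perm <- porous$spec$permeability
    if (!is.finite(k_perm) || k_perm <= 0)
      stop_vf("permeability must be positive",
              class = "ventriflow_validation_error")
    nu_over_k <- props$kinematic_viscosity / k_perm
    pv <- numeric(fem$nv)
    for (l in seq_len(d + 1L))
      pv <- pv + scatter_add(fem$cells[porous$cells, l],
                             fem$vol[porous$cells] / (d + 1), fem$nv)
    cdrag <- nu_over_k * pv / fem$m
  }
  structure(list(fem = fem, props = props, cfg = cfg, bcs = bcs,
                 maskV = maskV, pnodes = pnodes, pfree = pfree, A = A,
                 A_ff = A_ff, chol_S = chol_S, out_geo = out_geo,
                 svec = svec, bsv = bsv, cdrag = cdrag,
                 gauge_outlet = has_outlet && pinned),
            class = "flow_problem")
}

apply_velocity_bc <- function(prob, u, t) {
  for (bc in prob$bcs$dirichlet) {
    v <- bc$value(t)
    if (is.matrix(v)) u[bc$nodes, ] <- v
    else u[bc$nodes, ] <- matrix(v, length(bc$nodes), prob$fem$d, byrow = TRUE)
  }
  u
}

outlet_flux <- function(prob, u) {
  og <- prob$out_geo
  if (is.null(og)) return(0)
  uf <- (u[og$faces[, 1], , drop = FALSE] + u[og$faces[, 2], , drop = FALSE] +
           u[og$faces[, 3], , drop = FALSE]) / 3
  sum(rowSums(uf * og$normal))
}

# explicit momentum right-hand side (kinematic units), excluding pressure
momentum_rhs <- function(prob, u, t) {
  fem <- prob$fem
  nu <- prob$props$kinematic_viscosity
  F <- -assemble_nonlinear(fem, u, prob$cfg$nonlinear_form)
  for (k in seq_len(fem$d))
    F[, k] <- F[, k] - nu * as.vector(fem$L %*% u[, k])
  bf <- prob$bcs$body_force
  if (!is.null(bf) && any(bf != 0))
    for (k in seq_len(fem$d)) F[, k] <- F[, k] + fem$m * bf[k]
  og <- prob$out_geo
  if (!is.null(og)) {  # quadratic backflow penalty on the outlet
    uf <- (u[og$faces[, 1], , drop = FALSE] + u[og$faces[, 2], , drop = FALSE] +
             u[og$faces[, 3], , drop = FALSE]) / 3
    un <- rowSums(uf * og$unit_n)
    coef <- 0.5 * pmin(un, 0) * og$area / 3
    if (any(coef < 0)) {
      for (l in 1:3) for (k in seq_len(fem$d))
        F[, k] <- F[, k] + scatter_add(og$faces[, l], coef * uf[, k], fem$nv)
    }
  }
  F
}

#' Darcy drag force of a porous region
#'
#' Weak (lumped) drag `-(mu/k) u` restricted to the porous cells, returned as
#' a kinematic nodal force (divide by nodal mass for an acceleration).
#'
#' @param fem `fem_structure`
#' @param u nodal velocity (nv x d)
#' @param porous_cells porous cell indices
#' @param spec `porous_layer_spec` (provides the intrinsic permeability)
#' @param props `fluid_properties`
#' @return nodal force (nv x d)
#' @export
darcy_drag <- function(fem, u, porous_cells, spec, props = fluid_properties()) {
  if (!is.finite(spec$permeability) || spec$permeability <= 0)
    stop_vf("permeability must be positive",
            class = "ventriflow_validation_error")
  pv <- numeric(fem$nv)
  for (l in seq_len(fem$d + 1L))
    pv <- pv + scatter_add(fem$cells[porous_cells, l],
                           fem$vol[porous_cells] / (fem$d + 1), fem$nv)
  -(props$kinematic_viscosity / spec$permeability) * pv * u
}

#' Eigenvalue-bound time-step estimate
#'
#' `dt = cfl_safety / max_cells(|u|_max / h + C_d nu / h^2)` with `h` the
#' cell's minimum height, `|u|_max` the largest nodal speed on the cell
#' (a cell mean would underestimate the advection rate of node-localized
#' features) and `C_d = 4`.
#'
#' @param prob `flow_problem` (or `fem_structure` plus `props`)
#' @param u nodal velocity (nv x d)
#' @return dt, s (`Inf` when both velocity and viscosity vanish)
#' @export
estimate_timestep <- function(prob, u) {
  fem <- prob$fem
  h <- cell_min_height(fem)
  if (any(h <= 0))
    stop_vf("degenerate cell (zero height)", class = "ventriflow_mesh_error")
  sp <- sqrt(rowSums(u^2))
  um <- sp[fem$cells[, 1]]
  for (l in 2:(fem$d + 1L)) um <- pmax(um, sp[fem$cells[, l]])
  rate <- um / h + 4 * prob$props$kinematic_viscosity / h^2
  prob$cfg$cfl_safety / max(rate, 0)
}

cell_min_height <- function(fem) fem$h_cell

#' Advance a flow state by one time step
#'
#' SSP Runge-Kutta momentum advance with stage-wise boundary enforcement,
#' implicit diagonal Darcy drag, then the non-incremental pressure projection
#' (solved from scratch via the cached factorization). Verifies the weak
#' divergence invariant and detects blow-up.
#'
#' @param prob `flow_problem`
#' @param state `flow_state`
#' @param dt time step, s
#' @return advanced `flow_state`
#' @export
step_flow <- function(prob, state, dt) {
  fem <- prob$fem
  t0 <- state$time
  t1 <- t0 + dt
  Lop <- function(u, t) {
    F <- momentum_rhs(prob, u, t)
    F / fem$m
  }
  u <- state$u
  if (prob$cfg$rk_stages == 3L) {
    u1 <- apply_velocity_bc(prob, u + dt * Lop(u, t0), t1)
    u2 <- apply_velocity_bc(prob, 0.75 * u + 0.25 * (u1 + dt * Lop(u1, t1)),
                            t0 + dt / 2)
    u <- apply_velocity_bc(prob, u / 3 + (2 / 3) * (u2 + dt * Lop(u2, t0 + dt / 2)),
                           t1)
  } else {
    u1 <- apply_velocity_bc(prob, u + dt * Lop(u, t0), t1)
    u <- apply_velocity_bc(prob, 0.5 * (u + u1 + dt * Lop(u1, t1)), t1)
  }
  if (any(prob$cdrag > 0)) {
    u <- u / (1 + dt * prob$cdrag)
    u <- apply_velocity_bc(prob, u, t1)
  }
  if (!all(is.finite(u)))
    stop_vf("solution blew up (non-finite velocity) advancing from t = ",
            signif(t0, 6), " s", class = "ventriflow_solver_error")

  # non-incremental pressure projection
  q_out <- outlet_flux(prob, u)
  pval <- prob$bcs$pressure_value(t1, q_out)
  p <- numeric(fem$nv)
  p[prob$pnodes] <- pval
  divu <- weak_divergence(fem, u)
  rhs <- -divu / dt - as.vector(prob$A %*% p)
  if (!is.null(prob$bsv)) rhs <- rhs + prob$bsv * pval
  rhs <- rhs[prob$pfree]
  rnorm0 <- sqrt(sum(rhs^2))
  # Richardson refinement toward the compatible operator A, preconditioned
  # by the stabilized operator S = (1-a) A + a L. Well-conditioned modes
  # (pencil eigenvalue t away from 0) contract at rate a(1-t)/((1-a)t + a)
  # and reach the exact compatible projection; ill modes (t ~ 0) contract
  # barely at all, which the rate cutoff detects, leaving them at the
  # bounded stabilized response instead of pumping their enormous exact
  # velocity footprint. The optimality check below verifies the resulting
  # least-squares floor identity exactly.
  pf <- numeric(length(rhs))
  r <- rhs
  rnorm <- rnorm0
  it <- 0L
  if (rnorm0 > 0) {
    stall <- 0L
    for (it in 1:150) {
      prev <- rnorm
      pf <- pf + as.vector(Matrix::solve(prob$chol_S, r))
      r <- rhs - as.vector(prob$A_ff %*% pf)
      rnorm <- sqrt(sum(r^2))
      if (rnorm <= 1e-12 * rnorm0) break
      if (rnorm > 0.95 * prev) stall <- stall + 1L else stall <- 0L
      if (stall >= 2L) break
    }
    if (!is.finite(rnorm) || rnorm > rnorm0)
      stop_vf("pressure projection did not converge: relative residual ",
              signif(rnorm / rnorm0, 3), " after ", it, " iterations",
              class = "ventriflow_solver_error")
  }
  p[prob$pfree] <- p[prob$pfree] + pf
  if (isTRUE(prob$gauge_outlet)) {
    # with all boundary velocities prescribed the pressure level is
    # dynamically irrelevant; gauge it so the area-averaged outlet cap
    # pressure equals the outlet-model prediction
    og <- prob$out_geo
    pface <- (p[og$faces[, 1]] + p[og$faces[, 2]] + p[og$faces[, 3]]) / 3
    p <- p + (pval - sum(pface * og$area) / sum(og$area))
  }
  wfac <- dt * prob$maskV / fem$m
  for (k in seq_len(fem$d)) {
    gk <- as.vector(Matrix::t(fem$B[[k]]) %*% p)
    if (!is.null(prob$svec)) gk <- gk - prob$svec[, k] * pval
    u[, k] <- u[, k] + wfac * gk
  }
  u <- apply_velocity_bc(prob, u, t1)

  divu <- weak_divergence(fem, u)
  unorm <- sqrt(sum(fem$m * rowSums(u^2)))
  dnorm <- sqrt(sum(divu[prob$pfree]^2 / fem$m[prob$pfree]))
  consistent <- rnorm0 == 0 || sqrt(sum(r^2)) <= 1e-10 * rnorm0
  if (consistent) {
    if (unorm > 0 && dnorm / unorm > prob$cfg$projection_tolerance)
      stop_vf("projection failed: relative divergence residual ",
              signif(dnorm / unorm, 3), " exceeds tolerance ",
              prob$cfg$projection_tolerance, class = "ventriflow_solver_error")
  } else {
    # least-squares optimality: the achieved divergence must equal the
    # irreducible null-space floor, div_after = -dt r, to solver precision
    opt <- sqrt(sum((divu[prob$pfree] + dt * r)^2)) / (dt * rnorm0)
    if (opt > 1e-8)
      stop_vf("projection failed: divergence exceeds the boundary-data ",
              "floor by ", signif(opt, 3), " relative",
              class = "ventriflow_solver_error")
  }
  out <- flow_state(u, p, t1)
  out$div_rel <- if (unorm > 0) dnorm / unorm else 0
  out$proj_iters <- it
  out$proj_resid <- if (rnorm0 > 0) rnorm / rnorm0 else 0
  out
}

#' Run a transient simulation
#'
#' Starts from rest (or `state0`), advances with the estimated stable time
#' step, stores snapshots every `cfg$output_interval`, and samples probe
#' series (mean physical pressure over the probe node sets, outlet flux)
#' every step.
#'
#' @param prob `flow_problem`
#' @param probes optional `list(p_in = nodes, p_out = nodes)`
#' @param state0 optional initial `flow_state` (default: rest)
#' @return `flow_run` list: `snapshots` (flow_states), `series` (data.frame
#'   time/p_in/p_out/q_out), `config`
#' @export
solve_transient <- function(prob, probes = NULL, state0 = NULL) {
  fem <- prob$fem
  cfg <- prob$cfg
  state <- state0 %||% flow_state(matrix(0, fem$nv, fem$d), time = 0)
  state$u <- apply_velocity_bc(prob, state$u, state$time)
  snapshots <- list(state)
  next_out <- state$time + cfg$output_interval
  rho <- prob$props$density
  sample_probes <- function(s) {
    c(time = s$time,
      p_in = if (!is.null(probes$p_in)) mean(s$p[probes$p_in]) * rho else NA_real_,
      p_out = if (!is.null(probes$p_out)) mean(s$p[probes$p_out]) * rho else NA_real_,
      q_out = outlet_flux(prob, s$u),
      div_rel = s$div_rel %||% 0)
  }
  frame_samples <- function(s) {
    if (is.null(probes)) return(NULL)
    list(time = s$time,
         p_in = s$p[probes$p_in] * rho, p_out = s$p[probes$p_out] * rho)
  }
  series <- list(sample_probes(state))
  probe_frames <- list(frame_samples(state))
  while (state$time < cfg$max_time - 1e-12) {
    dt <- estimate_timestep(prob, state$u)
    dt <- min(dt, cfg$max_time - state$time, next_out - state$time)
    state <- step_flow(prob, state, dt)
    series[[length(series) + 1L]] <- sample_probes(state)
    if (state$time >= next_out - 1e-12) {
      snapshots[[length(snapshots) + 1L]] <- state
      probe_frames[[length(probe_frames) + 1L]] <- frame_samples(state)
      next_out <- next_out + cfg$output_interval
    }
  }
  structure(list(snapshots = snapshots,
                 series = as.data.frame(do.call(rbind, series)),
                 probe_frames = if (!is.null(probes)) probe_frames,
                 config = cfg), class = "flow_run")
}

#' Probe node sets inside the flow-development tubes
#'
#' Nodes within `probe_length` of each tube's end cap, measured along the
#' tube axis, and within the tube radius of the axis.
#'
#' @param mesh `volume_mesh` carrying `tube_info`
#' @param fem `fem_structure` built from the mesh
#' @param probe_length m (default 0.015)
#' @return list with `p_in` and `p_out` node index vectors
#' @export
tube_probes <- function(mesh, fem, probe_length = 0.015) {
  ti <- attr(mesh, "tube_info")
  if (is.null(ti) || is.null(ti$inlet) || is.null(ti$outlet))
    stop_vf("mesh lacks tube_info metadata for probe placement",
            class = "ventriflow_validation_error")
  sel <- function(tb) {
    rel <- sweep(fem$vertices, 2, tb$valve_center)
    ax <- as.vector(rel %*% unit(tb$axis))
    rad2 <- rowSums(rel * rel) - ax^2
    which(ax >= 0 & ax <= min(probe_length, tb$length) &
            rad2 <= tb$radius^2 * 1.21)
  }
  list(p_in = sel(ti$inlet), p_out = sel(ti$outlet))
}
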