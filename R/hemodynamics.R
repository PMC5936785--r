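# Outcome metrics of a flow run: Freedman-Diaconis histograms and the
# mode-based intra-ventricular pressure drop, wall shear stress statistics,
# Q-criterion fields and thresholded vortex-surface areas.

#' Freedman-Diaconis histogram of a scalar sample
#'
#' Bin width `2 IQR n^(-1/3)` (linear-interpolation quantiles), density
#' normalized to unit area. The mode is the center of the maximal-density
#' bin, ties broken toward the lower bin. A zero IQR falls back to a single
#' bin whose mode is the (median) sample value.
#'
#' @param samples numeric vector, n >= 2
#' @return `histogram_fd` list: `bin_edges`, `density`, `n_samples`,
#'   `bin_width`, `mode_value`, `median_value`
#' @export
fd_histogram <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2 || any(!is.finite(samples)))
    stop_vf("fd_histogram needs at least 2 finite samples",
            class = "ventriflow_validation_error")
  med <- median(samples)
  iqr <- diff(quantile(samples, c(0.25, 0.75), names = FALSE))
  if (iqr == 0) {
    width <- max(diff(range(samples)), 1)
    edges <- med + c(-0.5, 0.5) * width
    out <- list(bin_edges = edges, density = 1 / width, n_samples = n,
                bin_width = width, mode_value = med, median_value = med)
    return(structure(out, class = "histogram_fd"))
  }
  bw <- 2 * iqr * n^(-1 / 3)
  lo <- min(samples)
  nb <- max(1L, ceiling((max(samples) - lo) / bw))
  edges <- lo + bw * (0:nb)
  idx <- pmin(pmax(1L, findInterval(samples, edges, rightmost.closed = TRUE)),
              nb)
  counts <- tabulate(idx, nb)
  density <- counts / (n * bw)
  k <- which.max(density)  # ties resolve to the lower bin
  structure(list(bin_edges = edges, density = density, n_samples = n,
                 bin_width = bw, mode_value = lo + bw * (k - 0.5),
                 median_value = med), class = "histogram_fd")
}

#' Mode-based intra-ventricular pressure drop of a run
#'
#' Per saved frame, `delta P = mode(P_in) - mode(P_out)` from the
#' Freedman-Diaconis histograms of the nodal pressure samples inside the two
#' tube probe sub-volumes; returns the mean and standard deviation over the
#' last `window_frames` frames, in kPa.
#'
#' @param run `flow_run` produced with probes
#' @param window_frames averaging window in saved frames (default 10)
#' @return list with `delta_p` and `delta_p_sd` (kPa) and the per-frame
#'   series `delta_p_frames`
#' @export
pressure_drop <- function(run, window_frames = 10) {
  frames <- run$probe_frames
  if (is.null(frames))
    stop_vf("run record has no probe samples; rerun solve_transient with ",
            "probes", class = "ventriflow_validation_error")
  if (length(frames) < window_frames)
    stop_vf("pressure_drop needs at least ", window_frames,
            " saved frames, run has ", length(frames),
            class = "ventriflow_validation_error")
  dp <- vapply(frames, function(fr) {
    fd_histogram(fr$p_in)$mode_value - fd_histogram(fr$p_out)$mode_value
  }, numeric(1)) / 1000
  w <- tail(dp, window_frames)
  list(delta_p = mean(w), delta_p_sd = if (length(w) > 1) sd(w) else 0,
       delta_p_frames = dp)
}

# per-cell velocity gradient components du[[a]][[k]] = d u_a / dx_k
cell_gradients <- function(fem, u) {
  lapply(seq_len(fem$d), function(a)
    lapply(seq_len(fem$d), function(k) cell_deriv(fem, u[, a], k)))
}

#' Per-cell Q-criterion field
#'
#' `Q = (|W|_F^2 - |S|_F^2) / 2` with `S`/`W` the symmetric/antisymmetric
#' parts of the cell-wise velocity gradient.
#'
#' @param fem `fem_structure`
#' @param u nodal velocity (nv x d)
#' @return per-cell Q, 1/s^2
#' @export
q_criterion <- function(fem, u) {
  du <- cell_gradients(fem, u)
  q <- numeric(fem$nc)
  for (a in seq_len(fem$d)) for (k in seq_len(fem$d)) {
    s <- 0.5 * (du[[a]][[k]] + du[[k]][[a]])
    w <- 0.5 * (du[[a]][[k]] - du[[k]][[a]])
    q <- q + 0.5 * (w^2 - s^2)
  }
  q
}

#' Strain / rotation decomposition of the velocity gradient
#'
#' @param fem `fem_structure`
#' @param u nodal velocity (nv x d)
#' @return list with per-cell matrices `S` and `W` (each a d x d list of
#'   per-cell vectors) satisfying `S + W = grad u` exactly, and `Q`
#' @export
gradient_decomposition <- function(fem, u) {
  du <- cell_gradients(fem, u)
  S <- W <- vector("list", fem$d)
  for (a in seq_len(fem$d)) {
    S[[a]] <- W[[a]] <- vector("list", fem$d)
    for (k in seq_len(fem$d)) {
      S[[a]][[k]] <- 0.5 * (du[[a]][[k]] + du[[k]][[a]])
      W[[a]][[k]] <- 0.5 * (du[[a]][[k]] - du[[k]][[a]])
    }
  }
  list(S = S, W = W, Q = q_criterion(fem, u))
}

# map each boundary face of a volume mesh to its owning cell
boundary_face_cells <- function(mesh) {
  tets <- mesh$cells
  all_faces <- rbind(cbind(tets[, 1], tets[, 3], tets[, 2]),
                     cbind(tets[, 1], tets[, 2], tets[, 4]),
                     cbind(tets[, 2], tets[, 3], tets[, 4]),
                     cbind(tets[, 1], tets[, 4], tets[, 3]))
  owner <- rep(seq_len(nrow(tets)), 4)
  fkey <- function(f) paste(pmin(pmin(f[, 1], f[, 2]), f[, 3]),
                            f[, 1] + f[, 2] + f[, 3],
                            pmax(pmax(f[, 1], f[, 2]), f[, 3]))
  owner[match(fkey(mesh$boundary_faces), fkey(all_faces))]
}

#' Wall shear stress over the tagged wall faces
#'
#' Magnitude of the tangential component of the viscous traction
#' `2 mu S(u) n` on each wall boundary face, evaluated from the owning
#' cell's velocity gradient. The cavity summary (histogram, mode, median,
#' max) excludes tube-wall faces, identified as faces whose centroid lies on
#' or above the valve (base) plane when that metadata is present.
#'
#' @param fem `fem_structure` built from `mesh`
#' @param u nodal velocity (nv x d), m/s
#' @param mesh `volume_mesh` with wall tags
#' @param props `fluid_properties`
#' @return list: `wss` (Pa, per wall face), `cavity` logical mask,
#'   `informative` logical mask (owning cell has at least one interior
#'   vertex; only these faces enter the statistics), `histogram`,
#'   `wss_mode`, `wss_median`, `wss_max` over informative cavity faces
#' @export
wall_shear_stress <- function(fem, u, mesh, props = fluid_properties()) {
  wall <- which(mesh$boundary_tags == "wall")
  if (!length(wall))
    stop_vf("mesh has no wall-tagged boundary faces",
            class = "ventriflow_validation_error")
  faces <- mesh$boundary_faces[wall, , drop = FALSE]
  own <- boundary_face_cells(mesh)[wall]
  v0 <- mesh$vertices[faces[, 1], , drop = FALSE]
  nr <- cross3(mesh$vertices[faces[, 2], , drop = FALSE] - v0,
               mesh$vertices[faces[, 3], , drop = FALSE] - v0)
  nrm <- normalize_rows(nr)
  du <- cell_gradients(fem, u)
  mu <- props$dynamic_viscosity
  d <- fem$d
  tr <- matrix(0, length(wall), d)
  for (a in seq_len(d)) for (k in seq_len(d))
    tr[, a] <- tr[, a] +
      mu * (du[[a]][[k]][own] + du[[k]][[a]][own]) * nrm[, k]
  tn <- rowSums(tr * nrm)
  tt <- tr - tn * nrm
  wss <- row_norms(tt)
  bp <- attr(mesh, "base_plane")
  cavity <- rep(TRUE, length(wss))
  if (!is.null(bp)) {
    cen <- (mesh$vertices[faces[, 1], , drop = FALSE] +
              mesh$vertices[faces[, 2], , drop = FALSE] +
              mesh$vertices[faces[, 3], , drop = FALSE]) / 3
    h <- as.vector(sweep(cen, 2, bp$point) %*% bp$normal)
    cavity <- h < 0
  }
  # faces owned by cells whose vertices ALL lie on the boundary carry an
  # identically zero (no-slip) interpolant regardless of the flow: their
  # computed stress is a discretization artifact, not a measurement, so the
  # summary statistics use only informative faces (the per-face vector keeps
  # every wall face)
  onb <- rep(FALSE, fem$nv)
  onb[unique(as.vector(mesh$boundary_faces))] <- TRUE
  ncb <- rowSums(matrix(onb[fem$cells], ncol = fem$d + 1L))
  informative <- ncb[own] < fem$d + 1L
  cw <- wss[cavity & informative]
  if (!length(cw)) cw <- wss[cavity]
  hist <- if (length(cw) >= 2) fd_histogram(cw) else NULL
  list(wss = wss, cavity = cavity, informative = informative,
       histogram = hist,
       wss_mode = if (!is.null(hist)) hist$mode_value else NA_real_,
       wss_median = if (length(cw)) median(cw) else NA_real_,
       wss_max = if (length(cw)) max(cw) else NA_real_)
}

#' Total vortex-surface area at a Q-criterion threshold
#'
#' Interpolates the per-cell Q field to nodes by volume-weighted averaging,
#' extracts the `Q = threshold` isosurface by marching tetrahedra and sums
#' the triangle areas over all components.
#'
#' @param fem `fem_structure`
#' @param q_cell per-cell Q field
#' @param threshold 1/s^2 (finite)
#' @return area, m^2 (0 for an empty isosurface)
#' @export
vortex_surface <- function(fem, q_cell, threshold) {
  check_number(threshold, "threshold")
  num <- numeric(fem$nv)
  for (l in seq_len(fem$d + 1L))
    num <- num + scatter_add(fem$cells[, l], fem$vol * q_cell, fem$nv)
  qn <- num / (fem$m * (fem$d + 1))
  iso <- marching_tets(fem$vertices, fem$cells, qn, level = threshold)
  if (!nrow(iso$faces)) return(0)
  sum(face_areas(iso))
}

#' Hemodynamic summary of a transient run
#'
#' Combines the mode-based pressure drop, cavity wall-shear-stress
#' statistics of the final frame, and the total vortex-surface area of the
#' final frame at the given Q threshold.
#'
#' @param run `flow_run` (with probes for the pressure drop)
#' @param fem `fem_structure` of the run's mesh
#' @param mesh `volume_mesh`
#' @param q_threshold 1/s^2
#' @param props `fluid_properties`
#' @param window_frames pressure averaging window (default 10)
#' @return `hemodynamic_summary` list: `delta_p`, `delta_p_sd` (kPa),
#'   `wss_mode`, `wss_median`, `wss_max` (Pa), `total_vortex_surface` (m^2),
#'   `q_threshold`
#' @export
summarize_run <- function(run, fem, mesh, q_threshold,
                          props = fluid_properties(), window_frames = 10) {
  dp <- pressure_drop(run, window_frames)
  uT <- run$snapshots[[length(run$snapshots)]]$u
  wss <- wall_shear_stress(fem, uT, mesh, props)
  q <- q_criterion(fem, uT)
  structure(list(delta_p = dp$delta_p, delta_p_sd = dp$delta_p_sd,
                 wss_mode = wss$wss_mode, wss_median = wss$wss_median,
                 wss_max = wss$wss_max,
                 total_vortex_surface = vortex_surface(fem, q, q_threshold),
                 q_threshold = q_threshold), class = "hemodynamic_summary")
}
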