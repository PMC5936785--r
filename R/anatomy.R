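# Synthetic ventricle-like anatomy factory: a truncated half-ellipsoid cavity
# with a planar base carrying the mitral-side inlet orifice and aortic-side
# outlet orifice, each extended by a flow-development tube (50 mm inlet,
# 70 mm outlet by default). Trabeculation is synthesized as a seeded bump
# displacement field applied inward on the cavity wall.

#' Parameters of the smoothed ventricle-like cavity
#'
#' All lengths in meters. The cavity is a half-ellipsoid below the basal plane
#' z = 0 (apex at z = -long_axis_length); the two valve orifices sit on the
#' basal plane at `inlet_offset` / `outlet_offset` (x, y positions), with
#' tubes leaving along axes tilted from +z by the given tilt angles.
#'
#' @param long_axis_length apex-to-base distance, m
#' @param base_radius basal cross-section radius, m
#' @param inlet_offset,outlet_offset length-2 (x, y) valve-center positions on
#'   the basal plane, m
#' @param inlet_radius,outlet_radius orifice/tube radii, m (0 disables a tube)
#' @param inlet_tube_length,outlet_tube_length tube lengths, m (defaults 0.050
#'   and 0.070: flow-development tubes at the mitral and aortic orifices)
#' @param inlet_tilt,outlet_tilt length-2 tilt angles (degrees) of the tube
#'   axis: rotations about the x and y axes applied to +z
#' @param surface_resolution lattice spacing of the implicit-surface
#'   extraction, m
#' @return validated `cavity_params` list
#' @export
cavity_params <- function(long_axis_length = 0.08,
                          base_radius = 0.03,
                          inlet_offset = c(-0.013, 0),
                          outlet_offset = c(0.014, 0),
                          inlet_radius = 0.012,
                          outlet_radius = 0.009,
                          inlet_tube_length = 0.050,
                          outlet_tube_length = 0.070,
                          inlet_tilt = c(0, -12),
                          outlet_tilt = c(0, 28),
                          surface_resolution = 0.002) {
  p <- list(long_axis_length = long_axis_length, base_radius = base_radius,
            inlet_offset = inlet_offset, outlet_offset = outlet_offset,
            inlet_radius = inlet_radius, outlet_radius = outlet_radius,
            inlet_tube_length = inlet_tube_length,
            outlet_tube_length = outlet_tube_length,
            inlet_tilt = inlet_tilt, outlet_tilt = outlet_tilt,
            surface_resolution = surface_resolution)
  class(p) <- "cavity_params"
  validate_cavity_params(p)
  p
}

validate_cavity_params <- function(p) {
  check_number(p$long_axis_length, "long_axis_length", 0, strict_lower = TRUE)
  check_number(p$base_radius, "base_radius", 0, strict_lower = TRUE)
  check_number(p$inlet_radius, "inlet_radius", 0)
  check_number(p$outlet_radius, "outlet_radius", 0)
  check_number(p$inlet_tube_length, "inlet_tube_length", 0, strict_lower = TRUE)
  check_number(p$outlet_tube_length, "outlet_tube_length", 0, strict_lower = TRUE)
  check_number(p$surface_resolution, "surface_resolution", 0, strict_lower = TRUE)
  if (p$inlet_radius > 0 && p$outlet_radius > 0) {
    gap <- sqrt(sum((p$inlet_offset - p$outlet_offset)^2))
    if (gap < p$inlet_radius + p$outlet_radius)
      stop_vf("valve orifices overlap: |inlet_offset - outlet_offset| = ",
              signif(gap, 4), " < inlet_radius + outlet_radius = ",
              signif(p$inlet_radius + p$outlet_radius, 4),
              class = "ventriflow_geometry_error")
    for (side in c("inlet", "outlet")) {
      off <- p[[paste0(side, "_offset")]]
      r <- p[[paste0(side, "_radius")]]
      if (sqrt(sum(off^2)) + r > p$base_radius)
        stop_vf(side, " orifice does not fit inside the basal disc (",
                side, "_offset, ", side, "_radius, base_radius)",
                class = "ventriflow_geometry_error")
    }
  }
  invisible(p)
}

tilt_axis <- function(tilt) {
  ax <- tilt[1] * pi / 180
  ay <- tilt[2] * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  as.vector(Ry %*% Rx %*% c(0, 0, 1))
}

#' Build the smoothed (convex) ventricle-like surface with its tubes
#'
#' Extracts the zero level set of the union of a half-ellipsoid cavity and two
#' capped cylinders on a Freudenthal lattice, snaps the tube end caps onto
#' their exact planes (perpendicular to the tube axes), and labels faces as
#' `wall`, `inlet_cap` or `outlet_cap`. Tube base planes coincide with the
#' valve-ring planes on the basal plane of the cavity.
#'
#' @param params `cavity_params`
#' @return labelled watertight `surface_mesh`, with `tube_info` and
#'   `base_plane` metadata attributes
#' @export
build_smoothed_cavity <- function(params) {
  validate_cavity_params(params)
  p <- params
  h <- p$surface_resolution
  tubes <- list()
  if (p$inlet_radius > 0)
    tubes$inlet <- list(axis = tilt_axis(p$inlet_tilt),
                        valve_center = c(p$inlet_offset, 0),
                        radius = p$inlet_radius, length = p$inlet_tube_length)
  if (p$outlet_radius > 0)
    tubes$outlet <- list(axis = tilt_axis(p$outlet_tilt),
                         valve_center = c(p$outlet_offset, 0),
                         radius = p$outlet_radius, length = p$outlet_tube_length)
  sdf <- function(x) {
    v <- sdf_half_ellipsoid(x, p$base_radius, p$long_axis_length)
    for (tb in tubes)
      v <- pmin(v, sdf_tube(x, tb$valve_center, tb$axis, tb$radius, tb$length,
                            undershoot = 4 * h))
    v
  }
  corners <- rbind(c(-p$base_radius, -p$base_radius, -p$long_axis_length),
                   c(p$base_radius, p$base_radius, 0))
  for (tb in tubes) {
    tip <- tb$valve_center + tb$axis * tb$length
    corners <- rbind(corners, tip - 1.5 * tb$radius, tip + 1.5 * tb$radius)
  }
  bbox <- rbind(apply(corners, 2, min), apply(corners, 2, max))
  mesh <- extract_isosurface(sdf, bbox, h)

  labels <- rep("wall", nrow(mesh$faces))
  for (nm in names(tubes)) {
    tb <- tubes[[nm]]
    cap_c <- tb$valve_center + tb$axis * tb$length
    rel <- sweep(mesh$vertices, 2, cap_c)
    ax_d <- as.vector(rel %*% tb$axis)
    rad <- sqrt(pmax(rowSums(rel * rel) - ax_d^2, 0))
    snap <- abs(ax_d) < 0.75 * h & rad <= tb$radius + 0.5 * h
    mesh$vertices[snap, ] <- mesh$vertices[snap, , drop = FALSE] -
      outer(ax_d[snap], tb$axis)
    on_cap <- matrix(snap[mesh$faces], nrow(mesh$faces), 3)
    labels[rowSums(on_cap) == 3L] <- paste0(nm, "_cap")
    tubes[[nm]]$cap_center <- cap_c
  }
  out <- surface_mesh(mesh$vertices, mesh$faces, labels, tube_info = tubes)
  attr(out, "base_plane") <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  attr(out, "cavity_params") <- p
  out
}

#' Parameters of the synthetic trabeculation field
#'
#' Trabeculae are emulated as seeded Gaussian bump protrusions displacing the
#' cavity wall inward; papillary muscles as a few large protrusions in the
#' basal third. Bump width is tied to `min_cross_section` so protrusion necks
#' keep at least that cross-sectional area.
#'
#' @param amplitude protrusion depth scale, m
#' @param min_cross_section smallest protrusion neck cross-section, m^2
#'   (default 1e-6, i.e. 1 mm^2)
#' @param density protrusions per unit wall area, 1/m^2 (default 3e4: one
#'   bump per ~6 mm of wall, enough displaced volume to reach trabecular
#'   fractions of ~0.2 without inverting the surface)
#' @param target_volume_fraction fraction of the cavity volume the protrusions
#'   should occupy (0 disables calibration, < 0.5); when positive, the bump
#'   amplitude is rescaled so the displaced volume matches
#' @param papillary_count number of large papillary-muscle-like protrusions
#' @param papillary_scale size multiplier of papillary protrusions
#' @param seed integer seed of the bump random stream
#' @return validated `trabeculation_params`
#' @export
trabeculation_params <- function(amplitude = 0.004,
                                 min_cross_section = 1e-6,
                                 density = 3e4,
                                 target_volume_fraction = 0,
                                 papillary_count = 2,
                                 papillary_scale = 3,
                                 seed = 1L) {
  check_number(amplitude, "amplitude", 0)
  check_number(min_cross_section, "min_cross_section", 0, strict_lower = TRUE)
  check_number(density, "density", 0)
  check_number(target_volume_fraction, "target_volume_fraction", 0, 0.5,
               strict_upper = TRUE)
  check_number(papillary_count, "papillary_count", 0)
  structure(list(amplitude = amplitude, min_cross_section = min_cross_section,
                 density = density,
                 target_volume_fraction = target_volume_fraction,
                 papillary_count = as.integer(papillary_count),
                 papillary_scale = papillary_scale, seed = as.integer(seed)),
            class = "trabeculation_params")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Add synthetic trabeculae and papillary muscles to a smoothed cavity
#'
#' Displaces cavity-wall vertices (below the basal plane; tubes and caps are
#' never touched) along the inward smoothed-surface normals by a seeded sum of
#' Gaussian bumps plus `papillary_count` larger protrusions. If
#' `target_volume_fraction > 0`, a global displacement multiplier is calibrated
#' by secant iteration so the removed volume fraction matches. The operation is
#' a pure function of (surface, trab): identical seeds give byte-identical
#' output.
#'
#' @param surface `surface_mesh` from [build_smoothed_cavity()]
#' @param trab `trabeculation_params`
#' @return displaced `surface_mesh` (same connectivity and labels)
#' @export
add_trabeculation <- function(surface, trab) {
  stopifnot(inherits(surface, "surface_mesh"), inherits(trab, "trabeculation_params"))
  if (trab$amplitude == 0 && trab$target_volume_fraction == 0) return(surface)
  bp <- attr(surface, "base_plane")
  if (is.null(bp))
    stop_vf("surface lacks base_plane metadata; trabeculation needs a cavity ",
            "built by build_smoothed_cavity()")
  height <- as.vector(sweep(surface$vertices, 2, bp$point) %*% bp$normal)
  L <- -min(height)
  wall_vert <- rep(FALSE, nrow(surface$vertices))
  wall_vert[unique(as.vector(surface$faces[surface$face_labels == "wall", ]))] <- TRUE
  taper <- 0.12 * L
  w_base <- pmin(pmax(-height / taper, 0), 1)  # fades to 0 at the basal plane
  movable <- wall_vert & height < 0
  nrm <- vertex_normals(surface)

  areas <- face_areas(surface)
  wall_area <- sum(areas[surface$face_labels == "wall" &
                           height[surface$faces[, 1]] < 0])
  # bump width: at least the neck-radius scale, and wide enough that bumps
  # are resolvable on the mesh (narrower bumps alias into vertex-scale noise)
  e1 <- row_norms(face_vertex(surface, 2) - face_vertex(surface, 1))
  sigma <- max(1.5 * sqrt(trab$min_cross_section / pi), 2 * stats::median(e1))
  n_bumps <- max(1L, round(trab$density * wall_area))

  cand <- which(movable & height < -taper)
  field <- with_seed(trab$seed, {
    centers <- surface$vertices[sample(cand, min(n_bumps, length(cand))), ,
                                drop = FALSE]
    amp_mult <- runif(nrow(centers), 0.5, 1)
    basal <- cand[height[cand] > -0.45 * L & height[cand] < -0.15 * L]
    pm_centers <- surface$vertices[sample(basal, min(trab$papillary_count,
                                                     length(basal))), , drop = FALSE]
    f <- numeric(nrow(surface$vertices))
    vi <- surface$vertices[movable, , drop = FALSE]
    add_bumps <- function(f_part, ctrs, amps, sg) {
      for (b in seq_len(nrow(ctrs))) {
        d2 <- rowSums(sweep(vi, 2, ctrs[b, ])^2)
        f_part <- f_part + amps[b] * exp(-d2 / (2 * sg^2))
      }
      f_part
    }
    fm <- add_bumps(numeric(nrow(vi)), centers, amp_mult, sigma)
    if (nrow(pm_centers))
      fm <- add_bumps(fm, pm_centers,
                      rep(trab$papillary_scale, nrow(pm_centers)),
                      trab$papillary_scale * sigma)
    f[movable] <- fm
    f
  })
  # soft saturation: overlapping bumps stack, but protrusion depth should stay
  # bounded by a couple of amplitudes so deep stacks do not pierce the cavity
  field <- 2 * tanh(field / 2)
  disp_unit <- -nrm * (field * w_base)  # inward displacement per unit amplitude

  apply_disp <- function(lambda) {
    out <- surface
    out$vertices <- surface$vertices + lambda * trab$amplitude * disp_unit
    out
  }
  lambda <- 1
  if (trab$target_volume_fraction > 0) {
    cav <- cavity_face_subset(surface)
    V0 <- cavity_volume(surface, cav)
    frac <- function(l) (V0 - cavity_volume(apply_disp(l), cav)) / V0
    tgt <- trab$target_volume_fraction
    # bracket the target on [l_lo, l_hi]; the removed fraction is monotone in
    # the multiplier while the displaced surface stays injective, so loss of
    # monotonicity flags an unreachable target
    l_lo <- 0; f_lo <- 0
    l_hi <- 1; f_hi <- frac(1)
    while (f_hi < tgt) {
      if (f_hi <= f_lo || l_hi > 64)
        stop_vf("target_volume_fraction = ", tgt, " is unreachable for this ",
                "bump field (removed fraction stalled at ", signif(f_hi, 3),
                "); increase amplitude or density",
                class = "ventriflow_geometry_error")
      l_lo <- l_hi; f_lo <- f_hi
      l_hi <- 2 * l_hi; f_hi <- frac(l_hi)
    }
    for (it in 1:40) {
      l_mid <- 0.5 * (l_lo + l_hi)
      f_mid <- frac(l_mid)
      if (abs(f_mid - tgt) < 1e-3) { l_lo <- l_hi <- l_mid; break }
      if (f_mid < tgt) l_lo <- l_mid else l_hi <- l_mid
    }
    lambda <- 0.5 * (l_lo + l_hi)
  }
  out <- apply_disp(lambda)
  # validity: the normal-displacement map is injective while the displacement
  # stays well below the smooth surface's curvature radius (~ the cavity
  # depth scale), and no face may collapse to zero area
  max_disp <- lambda * trab$amplitude * max(row_norms(disp_unit))
  if (max_disp > 0.25 * L)
    stop_vf("trabeculation displacement reaches ", signif(max_disp, 3),
            " m, more than a quarter of the cavity depth; reduce amplitude ",
            "or target_volume_fraction", class = "ventriflow_geometry_error")
  if (min(face_areas(out)) < 1e-6 * stats::median(areas))
    stop_vf("displacement field collapsed surface faces to zero area; ",
            "reduce trabeculation amplitude and/or density",
            class = "ventriflow_geometry_error")
  out
}

# faces forming the cavity proper (centroid below the basal plane)
cavity_face_subset <- function(surface) {
  bp <- attr(surface, "base_plane")
  if (is.null(bp)) return(rep(TRUE, nrow(surface$faces)))
  hc <- as.vector(sweep(face_centroids(surface), 2, bp$point) %*% bp$normal)
  hc < 0
}

# enclosed volume of the cavity with tubes cut off at the basal plane: the
# divergence-theorem flux (x - p0)/3 vanishes on the (open) basal plane, so
# summing only cavity faces yields the volume of the plane-capped cavity
cavity_volume <- function(surface, subset = cavity_face_subset(surface)) {
  bp <- attr(surface, "base_plane")
  p0 <- if (is.null(bp)) c(0, 0, 0) else bp$point
  m <- surface
  m$vertices <- sweep(m$vertices, 2, p0)
  abs(enclosed_volume(m, subset))
}
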