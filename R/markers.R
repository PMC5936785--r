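#' Blood / fluid physical properties
#'
#' @param density kg/m^3 (default 1060, whole blood)
#' @param dynamic_viscosity kg/(m s) (default 0.0035, whole blood)
#' @param body_force external body force per unit mass, m/s^2 (length 3)
#' @param gravity gravitational acceleration, m/s^2; used only in the
#'   porosity-to-permeability conversion
#' @return `fluid_properties` with derived `kinematic_viscosity = mu/rho`
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.0035,
                             body_force = c(0, 0, 0), gravity = 9.81) {
  check_number(density, "fluid.density", 0, strict_lower = TRUE)
  check_number(dynamic_viscosity, "fluid.dynamic_viscosity", 0, strict_lower = TRUE)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity,
                 kinematic_viscosity = dynamic_viscosity / density,
                 body_force = body_force, gravity = gravity),
            class = "fluid_properties")
}

#' Inlet Reynolds number from orifice area
#'
#' Re = rho V D / mu with the equivalent circular diameter D = sqrt(4 A / pi).
#'
#' @param area inlet area, m^2
#' @param speed bulk inflow speed, m/s
#' @param props `fluid_properties`
#' @return dimensionless Reynolds number
#' @export
inlet_reynolds <- function(area, speed, props = fluid_properties()) {
  check_number(area, "area", 0, strict_lower = TRUE)
  check_number(speed, "speed", 0)
  D <- sqrt(4 * area / pi)
  props$density * speed * D / props$dynamic_viscosity
}

#' Geometric markers of a labelled ventricle-like surface
#'
#' Computes the trabecular volume percentage
#' `100 (V_hull - V_mesh) / V_hull` on the cavity with the flow-development
#' tubes cut off at the basal plane, the angle `alpha` (degrees) between the
#' two valve-plane normals, the distance `d` between the valve centers
#' (valve-ring centers when tube metadata is present, cap centroids
#' otherwise), the cap areas, and the inlet Reynolds number.
#'
#' @param surface labelled `surface_mesh` with `inlet_cap`/`outlet_cap` faces
#' @param fluid_speed bulk inlet speed used for the Reynolds number, m/s
#' @param props `fluid_properties`
#' @return `geometry_markers` list: trabecular_volume_pct, alpha, d,
#'   inlet_area, outlet_area, inlet_reynolds, cavity_volume, hull_volume
#' @export
compute_markers <- function(surface, fluid_speed = 0.55,
                            props = fluid_properties()) {
  labs <- surface$face_labels
  missing <- setdiff(c("inlet_cap", "outlet_cap"), unique(labs))
  if (length(missing))
    stop_vf("surface lacks cap labels: ", paste(missing, collapse = ", "),
            "; expected faces labelled inlet_cap and outlet_cap",
            class = "ventriflow_validation_error")
  areas <- face_areas(surface)
  cents <- face_centroids(surface)

  cap_data <- lapply(c("inlet_cap", "outlet_cap"), function(lb) {
    sel <- labs == lb
    a <- sum(areas[sel])
    ctr <- colSums(cents[sel, , drop = FALSE] * areas[sel]) / a
    nrm <- colSums(face_normals_raw(surface)[sel, , drop = FALSE])
    list(area = a, centroid = ctr, normal = unit(nrm))
  })
  names(cap_data) <- c("inlet", "outlet")

  ti <- attr(surface, "tube_info")
  if (!is.null(ti) && all(c("inlet", "outlet") %in% names(ti))) {
    d <- sqrt(sum((ti$inlet$valve_center - ti$outlet$valve_center)^2))
    n1 <- unit(ti$inlet$axis); n2 <- unit(ti$outlet$axis)
  } else {
    d <- sqrt(sum((cap_data$inlet$centroid - cap_data$outlet$centroid)^2))
    n1 <- cap_data$inlet$normal; n2 <- cap_data$outlet$normal
  }
  alpha <- acos(pmin(pmax(sum(n1 * n2), -1), 1)) * 180 / pi

  cav <- cavity_face_subset(surface)
  v_mesh <- cavity_volume(surface, cav)
  cav_pts <- surface$vertices[unique(as.vector(surface$faces[cav, , drop = FALSE])), ,
                              drop = FALSE]
  v_hull <- convex_hull3(cav_pts)$volume
  structure(list(
    trabecular_volume_pct = 100 * (v_hull - v_mesh) / v_hull,
    alpha = alpha, d = d,
    inlet_area = cap_data$inlet$area, outlet_area = cap_data$outlet$area,
    inlet_reynolds = inlet_reynolds(cap_data$inlet$area, fluid_speed, props),
    cavity_volume = v_mesh, hull_volume = v_hull), class = "geometry_markers")
}
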