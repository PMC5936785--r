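#' Triangulated surface mesh with boundary-role labels
#'
#' A `surface_mesh` is a closed, consistently oriented triangle mesh in SI
#' meters. Each face carries a label: `"wall"` for the endocardial (or generic)
#' surface, `"inlet_cap"` / `"outlet_cap"` for the planar tube end caps.
#' Optional metadata about the flow-development tubes (axes, radii, lengths,
#' valve-ring centers) is stored in the `tube_info` attribute and travels with
#' the object through rigid transforms.
#'
#' @param vertices numeric matrix (n x 3) of coordinates in meters
#' @param faces integer matrix (m x 3) of 1-based vertex indices, oriented so
#'   face normals point out of the enclosed volume
#' @param face_labels character vector of length m with values in
#'   `c("wall", "inlet_cap", "outlet_cap")`
#' @param tube_info optional list of per-tube metadata (see
#'   [build_smoothed_cavity()])
#' @return object of class `surface_mesh`
#' @export
surface_mesh <- function(vertices, faces, face_labels = NULL, tube_info = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop_vf("vertices must be n x 3")
  if (ncol(faces) != 3L) stop_vf("faces must be m x 3")
  if (is.null(face_labels)) face_labels <- rep("wall", nrow(faces))
  if (length(face_labels) != nrow(faces))
    stop_vf("face_labels must have one entry per face")
  bad <- setdiff(unique(face_labels), c("wall", "inlet_cap", "outlet_cap"))
  if (length(bad))
    stop_vf("unknown face labels: ", paste(bad, collapse = ", "))
  structure(list(vertices = vertices, faces = faces,
                 face_labels = as.character(face_labels)),
            tube_info = tube_info, class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces),
              paste(sprintf("%s: %d", names(table(x$face_labels)),
                            table(x$face_labels)), collapse = ", ")))
  invisible(x)
}

face_vertex <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Per-face unnormalized normals (outward, length = 2 x area)
#' @keywords internal
face_normals_raw <- function(mesh) {
  v0 <- face_vertex(mesh, 1)
  cross3(face_vertex(mesh, 2) - v0, face_vertex(mesh, 3) - v0)
}

#' Face areas of a surface mesh
#' @param mesh surface_mesh
#' @return numeric vector of face areas in m^2
#' @export
face_areas <- function(mesh) 0.5 * row_norms(face_normals_raw(mesh))

#' Face centroids of a surface mesh
#' @param mesh surface_mesh
#' @return m x 3 matrix
#' @export
face_centroids <- function(mesh) {
  (face_vertex(mesh, 1) + face_vertex(mesh, 2) + face_vertex(mesh, 3)) / 3
}

#' Enclosed volume of a closed surface by the divergence theorem
#'
#' Uses the flux of x/3 through the oriented surface, so the result is exact
#' for the polyhedron described by the mesh. A subset of faces may be selected;
#' faces omitted must then lie on planes through which the flux of x/3
#' vanishes for the result to equal an enclosed volume (used when cutting the
#' flow-development tubes off at the valve planes).
#'
#' @param mesh surface_mesh
#' @param subset optional logical/integer face subset
#' @return volume in m^3
#' @export
enclosed_volume <- function(mesh, subset = NULL) {
  f <- mesh$faces
  if (!is.null(subset)) f <- f[subset, , drop = FALSE]
  v0 <- mesh$vertices[f[, 1], , drop = FALSE]
  v1 <- mesh$vertices[f[, 2], , drop = FALSE]
  v2 <- mesh$vertices[f[, 3], , drop = FALSE]
  sum(v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) +
      v0[, 2] * (v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]) +
      v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])) / 6
}

#' Watertightness and orientation diagnostics for a surface mesh
#'
#' @param mesh surface_mesh
#' @return list with `watertight` (every undirected edge shared by exactly two
#'   faces), `oriented` (every directed half-edge used exactly once),
#'   `euler` (V - E + F), `min_area` (smallest face area)
#' @export
surface_check <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  und_tab <- table(key_und)
  nV <- length(unique(as.vector(f)))
  nE <- length(und_tab)
  list(watertight = all(und_tab == 2L),
       oriented = !anyDuplicated(key_dir),
       euler = nV - nE + nrow(f),
       min_area = min(face_areas(mesh)))
}

#' Apply a rigid-body transform to a surface mesh (metadata included)
#'
#' @param mesh surface_mesh
#' @param R 3x3 rotation matrix
#' @param t length-3 translation
#' @return transformed surface_mesh
#' @export
transform_surface <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  out <- mesh
  out$vertices <- mesh$vertices %*% t(R) + matrix(t, nrow(mesh$vertices), 3, byrow = TRUE)
  ti <- attr(mesh, "tube_info")
  if (!is.null(ti)) {
    for (nm in names(ti)) {
      ti[[nm]]$axis <- as.vector(R %*% ti[[nm]]$axis)
      ti[[nm]]$valve_center <- as.vector(R %*% ti[[nm]]$valve_center + t)
      ti[[nm]]$cap_center <- as.vector(R %*% ti[[nm]]$cap_center + t)
    }
    attr(out, "tube_info") <- ti
  }
  out
}

#' Area-weighted outward vertex normals
#' @keywords internal
vertex_normals <- function(mesh) {
  n <- face_normals_raw(mesh)
  out <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) for (d in 1:3)
    out[, d] <- out[, d] + scatter_add(mesh$faces[, k], n[, d], nrow(mesh$vertices))
  normalize_rows(out)
}
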