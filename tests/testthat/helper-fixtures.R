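# Shared fixtures, built lazily and cached for the whole test session.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- build()
  fixture_cache[[name]]
}

# smoothed cavity surface at the default resolution
fx_surface <- function() fixture("surface", function() {
  build_smoothed_cavity(cavity_params())
})

# coarse cavity volume mesh (fast; for IO / probe / layer tests)
fx_mesh <- function() fixture("mesh", function() {
  tetrahedralize(fx_surface(), max_cell_volume = (0.006)^3 / 6, jitter = 0)
})

fx_fem <- function() fixture("fem", function() {
  m <- fx_mesh()
  build_fem(m$vertices, m$cells)
})

# tiny watertight tetrahedron surface with all three labels (IO round trips)
fx_tet_surface <- function() surface_mesh(
  vertices = rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0), c(0, 0, 0.1)),
  faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
  face_labels = c("wall", "inlet_cap", "outlet_cap", "wall"))

# rowwise cross products of two matrices of 3-vectors (one row per triangle
# edge pair); each row's norm is twice the triangle area
cross3_area2 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

euler_characteristic <- function(surface) {
  e <- rbind(surface$faces[, c(1, 2)], surface$faces[, c(2, 3)],
             surface$faces[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  nrow(surface$vertices) - nrow(e) + nrow(surface$faces)
}
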