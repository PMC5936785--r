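# Implicit-geometry machinery: signed distance primitives, a Freudenthal
# lattice, and marching tetrahedra. Used both to synthesize the ventricle-like
# surfaces (zero level set of a signed distance field) and to extract
# Q-criterion isosurfaces from solver output.

#' Marching tetrahedra: extract the level-`level` isosurface of a nodal field
#'
#' The scalar field is taken piecewise-linear over each tetrahedron; crossing
#' points are placed by exact linear interpolation along edges, duplicate
#' points on shared edges are welded, and triangles are oriented so their
#' normals point toward increasing field values.
#'
#' @param vertices n x 3 node coordinates
#' @param tets m x 4 node indices
#' @param values nodal scalar values (length n)
#' @param level iso level
#' @return `surface_mesh` (all faces labelled "wall"); zero faces gives an
#'   empty mesh with 0 faces
#' @export
marching_tets <- function(vertices, tets, values, level = 0) {
  s <- values - level
  scale <- max(abs(s), .Machine$double.eps)
  s[s == 0] <- -1e-12 * scale
  inside <- s < 0
  m <- matrix(inside[tets], nrow(tets), 4)
  cnt <- rowSums(m)
  sel <- which(cnt > 0 & cnt < 4)
  if (!length(sel))
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), character(0)))
  code <- (m[sel, 1] + 2L * m[sel, 2] + 4L * m[sel, 3] + 8L * m[sel, 4])

  # triangle table: per 4-bit inside-pattern, triangles as pairs of local
  # vertex indices (a,b) per corner, referencing the cut edge a-b
  tri_for_code <- function(cd) {
    ins <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0L)
    out <- setdiff(1:4, ins)
    if (length(ins) == 1L) {
      i <- ins
      list(rbind(c(i, out[1]), c(i, out[2]), c(i, out[3])))
    } else if (length(ins) == 3L) {
      i <- out
      list(rbind(c(ins[1], i), c(ins[2], i), c(ins[3], i)))
    } else {
      i <- ins[1]; j <- ins[2]; k <- out[1]; l <- out[2]
      list(rbind(c(i, k), c(i, l), c(j, l)),
           rbind(c(i, k), c(j, l), c(j, k)))
    }
  }

  ea_blocks <- list(); eb_blocks <- list(); tet_blocks <- list(); bi <- 0L
  for (cd in sort(unique(code))) {
    rows <- sel[code == cd]
    for (tr in tri_for_code(cd)) {
      bi <- bi + 1L
      ea_blocks[[bi]] <- cbind(tets[rows, tr[1, 1]], tets[rows, tr[2, 1]],
                               tets[rows, tr[3, 1]])
      eb_blocks[[bi]] <- cbind(tets[rows, tr[1, 2]], tets[rows, tr[2, 2]],
                               tets[rows, tr[3, 2]])
      tet_blocks[[bi]] <- rows
    }
  }
  ea <- do.call(rbind, ea_blocks)  # ntri x 3 edge start nodes
  eb <- do.call(rbind, eb_blocks)
  tri_tet <- unlist(tet_blocks)
  ntri <- length(tri_tet)
  ea <- as.vector(t(ea)); eb <- as.vector(t(eb))  # triangle-major order
  t_ <- s[ea] / (s[ea] - s[eb])
  pts <- vertices[ea, , drop = FALSE] +
    t_ * (vertices[eb, , drop = FALSE] - vertices[ea, , drop = FALSE])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts_out <- pts[uk, , drop = FALSE]
  faces <- matrix(vid, ntri, 3, byrow = TRUE)
  tri_tet_all <- tri_tet

  # weld near-coincident crossing points (crossings passing close to a common
  # lattice node produce sliver triangles with near-zero area); cluster on a
  # grid of 2% of the typical edge length and drop collapsed faces
  el <- row_norms(verts_out[faces[, 2], , drop = FALSE] -
                    verts_out[faces[, 1], , drop = FALSE])
  tol <- 0.02 * stats::median(el)
  if (is.finite(tol) && tol > 0) {
    gkey <- paste(round(verts_out[, 1] / tol), round(verts_out[, 2] / tol),
                  round(verts_out[, 3] / tol))
    rep_id <- match(gkey, gkey[!duplicated(gkey)])
    first <- which(!duplicated(gkey))
    verts_w <- verts_out[first, , drop = FALSE]
    faces_w <- matrix(rep_id[faces], nrow(faces), 3)
    keep <- faces_w[, 1] != faces_w[, 2] & faces_w[, 2] != faces_w[, 3] &
      faces_w[, 3] != faces_w[, 1]
    # collapsing slivers can leave cancelling "fin" pairs: the same vertex
    # triple traversed twice; both copies enclose zero volume, drop them
    tkey <- apply(faces_w, 1, function(r) paste(sort(r), collapse = " "))
    keep <- keep & !(tkey %in% tkey[duplicated(tkey)])
    faces <- faces_w[keep, , drop = FALSE]
    tri_tet_all <- tri_tet_all[keep]
    used <- sort(unique(as.vector(faces)))
    faces <- matrix(match(faces, used), ncol = 3)
    verts_out <- verts_w[used, , drop = FALSE]
  }

  # orient each triangle along the parent tet's (constant) field gradient
  g <- tet_gradients(vertices, tets[tri_tet_all, , drop = FALSE], s)
  v0 <- verts_out[faces[, 1], , drop = FALSE]
  nrm <- cross3(verts_out[faces[, 2], , drop = FALSE] - v0,
                verts_out[faces[, 3], , drop = FALSE] - v0)
  flip <- rowSums(nrm * g) < 0
  faces[flip, ] <- faces[flip, c(1, 3, 2)]

  # the gradient test is unreliable for near-degenerate faces (normal is
  # numerical noise); repair residual winding conflicts against the larger
  # (trustworthy) neighbor until every directed half-edge is used once
  for (pass in 1:20) {
    nf <- nrow(faces)
    he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    kd <- paste(he[, 1], he[, 2])
    dup <- unique(kd[duplicated(kd)])
    if (!length(dup)) break
    v0 <- verts_out[faces[, 1], , drop = FALSE]
    ar <- row_norms(cross3(verts_out[faces[, 2], , drop = FALSE] - v0,
                           verts_out[faces[, 3], , drop = FALSE] - v0))
    to_flip <- rep(FALSE, nf)
    for (k in dup) {
      fr <- unique(((which(kd == k) - 1L) %% nf) + 1L)
      to_flip[fr[which.min(ar[fr])]] <- TRUE
    }
    faces[to_flip, ] <- faces[to_flip, c(1, 3, 2)]
  }
  surface_mesh(verts_out, faces)
}

# constant gradient of a nodal scalar field on each given tet
tet_gradients <- function(vertices, tets, s) {
  p0 <- vertices[tets[, 1], , drop = FALSE]
  e1 <- vertices[tets[, 2], , drop = FALSE] - p0
  e2 <- vertices[tets[, 3], , drop = FALSE] - p0
  e3 <- vertices[tets[, 4], , drop = FALSE] - p0
  d1 <- s[tets[, 2]] - s[tets[, 1]]
  d2 <- s[tets[, 3]] - s[tets[, 1]]
  d3 <- s[tets[, 4]] - s[tets[, 1]]
  # solve J^T g = d for each tet, J rows e1,e2,e3 (g = J^-T d)
  c23 <- cross3(e2, e3); c31 <- cross3(e3, e1); c12 <- cross3(e1, e2)
  det <- rowSums(e1 * c23)
  (d1 * c23 + d2 * c31 + d3 * c12) / det
}

# Freudenthal split of a cube into 6 tets; offsets in lattice units.
# Each tet: (0,0,0), +e_p1, +e_p1+e_p2, +(1,1,1) for permutations p of axes.
freudenthal_offsets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(seq_len(6), function(r) {
    p <- perms[r, ]
    o <- matrix(0L, 4, 3)
    o[2, p[1]] <- 1L
    o[3, p[1]] <- 1L; o[3, p[2]] <- 1L
    o[4, ] <- 1L
    o
  })
}

#' Extract the zero isosurface of an implicit function on a lattice
#'
#' Evaluates `f` on a regular lattice over `bbox` (expanded by one spacing of
#' margin), splits sign-crossing lattice cubes into six conforming tetrahedra,
#' and runs [marching_tets()]. `f` must be vectorized: it receives an n x 3
#' matrix and returns n signed values (negative inside).
#'
#' @param f implicit function (negative inside the body)
#' @param bbox 2 x 3 matrix: rows are lower and upper corners
#' @param h lattice spacing in meters
#' @return `surface_mesh`
#' @export
extract_isosurface <- function(f, bbox, h) {
  lo <- bbox[1, ] - 1.5 * h
  hi <- bbox[2, ] + 1.5 * h
  nx <- pmax(2L, as.integer(ceiling((hi - lo) / h)) + 1L)
  xs <- lapply(1:3, function(d) lo[d] + (seq_len(nx[d]) - 1) * h)
  pts <- as.matrix(expand.grid(x = xs[[1]], y = xs[[2]], z = xs[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  vals <- f(pts)
  A <- array(vals < 0, dim = nx)
  cs <- function(i, j, k) A[i, j, k, drop = FALSE]
  i <- seq_len(nx[1] - 1L); j <- seq_len(nx[2] - 1L); k <- seq_len(nx[3] - 1L)
  acc <- cs(i, j, k) + cs(i + 1L, j, k) + cs(i, j + 1L, k) + cs(i + 1L, j + 1L, k) +
    cs(i, j, k + 1L) + cs(i + 1L, j, k + 1L) + cs(i, j + 1L, k + 1L) +
    cs(i + 1L, j + 1L, k + 1L)
  mixed <- which(acc > 0 & acc < 8, arr.ind = TRUE)
  if (!nrow(mixed))
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), character(0)))
  nid <- function(ijk) ijk[, 1] + (ijk[, 2] - 1L) * nx[1] + (ijk[, 3] - 1L) * nx[1] * nx[2]
  tets <- do.call(rbind, lapply(freudenthal_offsets(), function(o) {
    cbind(nid(sweep(mixed, 2, o[1, ], "+")), nid(sweep(mixed, 2, o[2, ], "+")),
          nid(sweep(mixed, 2, o[3, ], "+")), nid(sweep(mixed, 2, o[4, ], "+")))
  }))
  marching_tets(pts, tets, vals, 0)
}

# ---- signed-distance primitives -------------------------------------------

#' Approximate signed distance to an axis-aligned half-ellipsoid cavity
#'
#' Half-ellipsoid with planar base at z = 0, apex at z = -long_axis, circular
#' cross-section of radius `base_radius`. Negative inside.
#' @keywords internal
sdf_half_ellipsoid <- function(p, base_radius, long_axis) {
  r <- sqrt((p[, 1] / base_radius)^2 + (p[, 2] / base_radius)^2 +
              (p[, 3] / long_axis)^2)
  fe <- (r - 1) * min(base_radius, long_axis)
  pmax(fe, p[, 3])
}

#' Signed distance to a capped cylinder (tube)
#'
#' Tube of radius `radius` from `base` along unit `axis` for `length` meters,
#' extended `undershoot` meters behind the base so unions with the cavity are
#' clean. Negative inside.
#' @keywords internal
sdf_tube <- function(p, base, axis, radius, length, undershoot = 0) {
  rel <- sweep(p, 2, base)
  z <- rel %*% axis
  rad <- sqrt(pmax(rowSums(rel * rel) - z^2, 0))
  a <- rad - radius
  half <- (length + undershoot) / 2
  b <- abs(z - (length - undershoot) / 2) - half
  pmin(pmax(a, b), 0) + sqrt(pmax(a, 0)^2 + pmax(b, 0)^2)
}
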