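# Tetrahedral volume mesher: lattice stuffing of a watertight labelled
# surface. Lattice cubes are split into six Freudenthal tetrahedra; a
# tetrahedron belongs to the fluid domain when its centroid lies inside the
# surface (vertical-ray parity test). Centroid classification makes the
# boundary error alternate in sign, so enclosed volume converges faster than
# a node-based staircase, and a cube whose surface coincides with lattice
# planes is filled exactly.

#' Tetrahedral volume mesh with boundary tags and cell regions
#'
#' @param vertices n x 3 node coordinates, m
#' @param cells m x 4 tetrahedra (positive signed volume)
#' @param boundary_faces b x 3 triangles, oriented outward
#' @param boundary_tags character vector, values in `c("inlet", "outlet", "wall")`
#' @param cell_region character vector per cell, values in `c("fluid", "porous")`
#' @return object of class `volume_mesh`
#' @export
volume_mesh <- function(vertices, cells, boundary_faces, boundary_tags,
                        cell_region = rep("fluid", nrow(cells))) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  cells <- as.matrix(cells); storage.mode(cells) <- "integer"
  boundary_faces <- as.matrix(boundary_faces)
  storage.mode(boundary_faces) <- "integer"
  if (ncol(cells) != 4L) stop_vf("cells must be m x 4")
  bad <- setdiff(unique(boundary_tags), c("inlet", "outlet", "wall"))
  if (length(bad)) stop_vf("unknown boundary tags: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(cell_region), c("fluid", "porous"))
  if (length(bad)) stop_vf("unknown cell regions: ", paste(bad, collapse = ", "))
  m <- structure(list(vertices = vertices, cells = cells,
                      boundary_faces = boundary_faces,
                      boundary_tags = as.character(boundary_tags),
                      cell_region = as.character(cell_region)),
                 class = "volume_mesh")
  vol <- cell_volumes(m)
  if (any(vol <= 0))
    stop_vf(sum(vol <= 0), " tetrahedra have non-positive volume",
            class = "ventriflow_mesh_error")
  m
}

#' @export
print.volume_mesh <- function(x, ...) {
  tb <- table(x$boundary_tags)
  cat(sprintf("volume_mesh: %d nodes, %d tets (%d porous), boundary %s\n",
              nrow(x$vertices), nrow(x$cells), sum(x$cell_region == "porous"),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Signed volumes of the tetrahedra of a volume mesh
#' @param mesh volume_mesh
#' @return numeric vector, m^3
#' @export
cell_volumes <- function(mesh) {
  p0 <- mesh$vertices[mesh$cells[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$cells[, 2], , drop = FALSE] - p0
  e2 <- mesh$vertices[mesh$cells[, 3], , drop = FALSE] - p0
  e3 <- mesh$vertices[mesh$cells[, 4], , drop = FALSE] - p0
  rowSums(e1 * cross3(e2, e3)) / 6
}

#' Cell centroids of a volume mesh
#' @param mesh volume_mesh
#' @return m x 3 matrix
#' @export
cell_centroids <- function(mesh) {
  (mesh$vertices[mesh$cells[, 1], , drop = FALSE] +
     mesh$vertices[mesh$cells[, 2], , drop = FALSE] +
     mesh$vertices[mesh$cells[, 3], , drop = FALSE] +
     mesh$vertices[mesh$cells[, 4], , drop = FALSE]) / 4
}

# parity-based point-in-surface test for a batch of query points; casts a
# vertical (+z) ray per point and counts transversal crossings below the point
points_inside_surface <- function(surface, query) {
  nq <- nrow(query)
  if (!nq) return(logical(0))
  v1 <- face_vertex(surface, 1); v2 <- face_vertex(surface, 2)
  v3 <- face_vertex(surface, 3)
  fxmin <- pmin(v1[, 1], v2[, 1], v3[, 1]); fxmax <- pmax(v1[, 1], v2[, 1], v3[, 1])
  fymin <- pmin(v1[, 2], v2[, 2], v3[, 2]); fymax <- pmax(v1[, 2], v2[, 2], v3[, 2])
  hbin <- max(stats::median(fxmax - fxmin), stats::median(fymax - fymin),
              .Machine$double.eps) * 4
  # deterministic sub-bin jitter dodges edge-on ray hits
  jit <- ((sin(seq_len(nq) * 78.233) * 43758.5453) %% 1 - 0.5) * 1e-6 * hbin
  qx <- query[, 1] + jit; qy <- query[, 2] + jit * 0.7

  fb <- data.table::data.table(
    face = seq_len(nrow(surface$faces)),
    bx_lo = floor(fxmin / hbin), bx_hi = floor(fxmax / hbin),
    by_lo = floor(fymin / hbin), by_hi = floor(fymax / hbin))
  fb <- fb[, {
    bxs <- seq.int(bx_lo, bx_hi); bys <- seq.int(by_lo, by_hi)
    list(bx = rep(bxs, each = length(bys)), by = rep(bys, length(bxs)))
  }, by = "face"]
  qb <- data.table::data.table(q = seq_len(nq), bx = floor(qx / hbin),
                               by = floor(qy / hbin))
  cand <- fb[qb, on = c("bx", "by"), allow.cartesian = TRUE, nomatch = NULL]
  inside <- logical(nq)
  if (!nrow(cand)) return(inside)
  f <- cand$face; q <- cand$q
  x <- qx[q]; y <- qy[q]
  ax <- v1[f, 1]; ay <- v1[f, 2]; bx_ <- v2[f, 1]; by_ <- v2[f, 2]
  cx <- v3[f, 1]; cy <- v3[f, 2]
  d1 <- (x - bx_) * (ay - by_) - (ax - bx_) * (y - by_)
  d2 <- (x - cx) * (by_ - cy) - (bx_ - cx) * (y - cy)
  d3 <- (x - ax) * (cy - ay) - (cx - ax) * (y - ay)
  hit <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
  den <- d1 + d2 + d3
  hit <- hit & abs(den) > 0
  if (!any(hit)) return(inside)
  f <- f[hit]; q <- q[hit]
  w1 <- d2[hit] / den[hit]; w2 <- d3[hit] / den[hit]; w3 <- d1[hit] / den[hit]
  zc <- w1 * v1[f, 3] + w2 * v2[f, 3] + w3 * v3[f, 3]
  below <- zc < query[q, 3]
  cnt <- scatter_add(q[below], rep(1, sum(below)), nq)
  inside[cnt %% 2 == 1] <- TRUE
  inside
}

#' Tetrahedralize a watertight labelled surface by lattice stuffing
#'
#' Splits an axis-aligned lattice into six tetrahedra per cube and keeps the
#' tetrahedra whose centroid lies inside the surface. The lattice spacing is
#' snapped per axis so the bounding box is partitioned exactly (a box whose
#' faces lie on lattice planes is filled to machine precision). Boundary faces
#' inherit `inlet`/`outlet`/`wall` tags from the nearest labelled surface
#' face. With `near_wall_refinement > 1`, cells touching the wall are halved
#' by conforming longest-edge bisection until their volume is below
#' `interior volume / near_wall_refinement`.
#'
#' @param surface watertight `surface_mesh` with cap labels
#' @param max_cell_volume upper cell-volume bound, m^3; sets the lattice
#'   spacing h = (6 max)^(1/3)
#' @param min_cell_volume lower cell-volume bound, m^3 (validated against the
#'   refined cell volume)
#' @param near_wall_refinement volume-reduction factor for wall-adjacent
#'   cells (1 disables refinement)
#' @param jitter deterministic lattice-node perturbation amplitude, relative
#'   to the spacing (default 0.15, 0 disables). A perfectly regular lattice
#'   admits exact checkerboard pressure modes of the equal-order projection
#'   operator; the jitter breaks the symmetry so the pressure system is
#'   definite on the free nodes.
#' @param jitter_seed seed of the (RNG-state-preserving) jitter draw
#' @return `volume_mesh` (all cells `fluid`); carries the surface's
#'   `base_plane` and `tube_info` attributes when present
#' @export
tetrahedralize <- function(surface, max_cell_volume,
                           min_cell_volume = 0, near_wall_refinement = 1,
                           jitter = 0.15, jitter_seed = 1L) {
  check_number(max_cell_volume, "max_cell_volume", 0, strict_lower = TRUE)
  check_number(min_cell_volume, "min_cell_volume", 0)
  check_number(near_wall_refinement, "near_wall_refinement", 1)
  check_number(jitter, "jitter", 0, 0.3)
  sc <- surface_check(surface)
  if (!sc$watertight || !sc$oriented)
    stop_vf("surface is not watertight/oriented; refusing to mesh",
            class = "ventriflow_mesh_error")
  h <- (6 * max_cell_volume)^(1 / 3)
  lo <- apply(surface$vertices, 2, min)
  hi <- apply(surface$vertices, 2, max)
  ext <- hi - lo
  if (any(ext <= 0)) stop_vf("degenerate surface bounding box")
  nx <- pmax(1L, as.integer(round(ext / h)))
  hs <- ext / nx  # per-axis snapped spacing
  nn <- nx + 1L
  xs <- lapply(1:3, function(d) lo[d] + (0:nx[d]) * hs[d])
  nid <- function(ijk) ijk[, 1] + (ijk[, 2] - 1L) * nn[1] +
    (ijk[, 3] - 1L) * nn[1] * nn[2]
  cubes <- as.matrix(expand.grid(i = seq_len(nx[1]), j = seq_len(nx[2]),
                                 k = seq_len(nx[3]), KEEP.OUT.ATTRS = FALSE))
  tets <- do.call(rbind, lapply(freudenthal_offsets(), function(o) {
    cbind(nid(sweep(cubes, 2, o[1, ], "+")), nid(sweep(cubes, 2, o[2, ], "+")),
          nid(sweep(cubes, 2, o[3, ], "+")), nid(sweep(cubes, 2, o[4, ], "+")))
  }))
  pts <- as.matrix(expand.grid(x = xs[[1]], y = xs[[2]], z = xs[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  if (jitter > 0) {
    dp <- with_seed(jitter_seed,
                    matrix(runif(length(pts), -jitter, jitter), ncol = 3))
    pts <- pts + dp * rep(hs, each = nrow(pts))
  }
  ctr <- (pts[tets[, 1], , drop = FALSE] + pts[tets[, 2], , drop = FALSE] +
            pts[tets[, 3], , drop = FALSE] + pts[tets[, 4], , drop = FALSE]) / 4
  keep <- points_inside_surface(surface, ctr)
  if (!any(keep))
    stop_vf("no tetrahedron centroid falls inside the surface; ",
            "max_cell_volume too coarse for this geometry",
            class = "ventriflow_mesh_error")
  tets <- tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  tets <- matrix(match(tets, used), ncol = 4)
  verts <- pts[used, , drop = FALSE]

  # orient all tets positive
  e1 <- verts[tets[, 2], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  e2 <- verts[tets[, 3], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  e3 <- verts[tets[, 4], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  neg <- rowSums(e1 * cross3(e2, e3)) < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]

  bnd <- boundary_of_tets(tets)
  tags <- inherit_boundary_tags(surface, verts, bnd)

  if (near_wall_refinement > 1) {
    wall_nodes <- unique(as.vector(bnd[tags == "wall", , drop = FALSE]))
    ref <- refine_near_wall(verts, tets, wall_nodes, near_wall_refinement)
    verts <- ref$vertices; tets <- ref$cells
    bnd <- boundary_of_tets(tets)
    tags <- inherit_boundary_tags(surface, verts, bnd)
  }
  mesh <- volume_mesh(verts, tets, bnd, tags)
  if (min_cell_volume > 0 && min(cell_volumes(mesh)) < min_cell_volume)
    stop_vf("refined cell volume falls below min_cell_volume; widen the ",
            "sizing band", class = "ventriflow_mesh_error")
  attr(mesh, "base_plane") <- attr(surface, "base_plane")
  attr(mesh, "tube_info") <- attr(surface, "tube_info")
  mesh
}

#' Structured tetrahedral mesh of an axis-aligned box
#'
#' Freudenthal (6 tets per cube) lattice over `[0, lengths]`, all boundary
#' faces tagged `"wall"`. Intended for validation geometries with known
#' closed-form fields.
#'
#' @param n integer vector of cells per axis (length 3, or a scalar)
#' @param lengths box edge lengths, m (length 3, or a scalar)
#' @return `volume_mesh`
#' @export
box_mesh <- function(n, lengths = 1) {
  n <- as.integer(rep_len(n, 3))
  lengths <- rep_len(as.numeric(lengths), 3)
  if (any(n < 1) || any(!is.finite(lengths)) || any(lengths <= 0))
    stop_vf("box_mesh needs n >= 1 and positive lengths",
            class = "ventriflow_validation_error")
  nn <- n + 1L
  hs <- lengths / n
  nid <- function(ijk) ijk[, 1] + (ijk[, 2] - 1L) * nn[1] +
    (ijk[, 3] - 1L) * nn[1] * nn[2]
  cubes <- as.matrix(expand.grid(i = seq_len(n[1]), j = seq_len(n[2]),
                                 k = seq_len(n[3]), KEEP.OUT.ATTRS = FALSE))
  tets <- do.call(rbind, lapply(freudenthal_offsets(), function(o) {
    cbind(nid(sweep(cubes, 2, o[1, ], "+")), nid(sweep(cubes, 2, o[2, ], "+")),
          nid(sweep(cubes, 2, o[3, ], "+")), nid(sweep(cubes, 2, o[4, ], "+")))
  }))
  pts <- as.matrix(expand.grid(x = (0:n[1]) * hs[1], y = (0:n[2]) * hs[2],
                               z = (0:n[3]) * hs[3], KEEP.OUT.ATTRS = FALSE))
  e1 <- pts[tets[, 2], , drop = FALSE] - pts[tets[, 1], , drop = FALSE]
  e2 <- pts[tets[, 3], , drop = FALSE] - pts[tets[, 1], , drop = FALSE]
  e3 <- pts[tets[, 4], , drop = FALSE] - pts[tets[, 1], , drop = FALSE]
  neg <- rowSums(e1 * cross3(e2, e3)) < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  bnd <- boundary_of_tets(tets)
  volume_mesh(pts, tets, bnd, rep("wall", nrow(bnd)))
}

# outward-oriented boundary faces of a positively oriented tet set
boundary_of_tets <- function(tets) {
  fc <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
              tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  key <- paste(pmin(fc[, 1], pmin(fc[, 2], fc[, 3])),
               fc[, 1] + fc[, 2] + fc[, 3],
               pmax(fc[, 1], pmax(fc[, 2], fc[, 3])))
  once <- !(key %in% key[duplicated(key)])
  fc[once, , drop = FALSE]
}

# nearest labelled surface face per boundary-face centroid (binned search)
inherit_boundary_tags <- function(surface, verts, bnd) {
  qc <- (verts[bnd[, 1], , drop = FALSE] + verts[bnd[, 2], , drop = FALSE] +
           verts[bnd[, 3], , drop = FALSE]) / 3
  sc <- face_centroids(surface)
  idx <- nearest_index(sc, qc)
  map <- c(wall = "wall", inlet_cap = "inlet", outlet_cap = "outlet")
  unname(map[surface$face_labels[idx]])
}

#' Nearest-reference index per query point (uniform-grid accelerated)
#' @keywords internal
nearest_index <- function(ref, query) {
  nq <- nrow(query)
  bb <- apply(rbind(ref, query), 2, range)
  hbin <- max(bb[2, ] - bb[1, ]) / 25
  if (hbin <= 0) hbin <- 1
  key3 <- function(p) paste(floor(p[, 1] / hbin), floor(p[, 2] / hbin),
                            floor(p[, 3] / hbin))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  rb <- data.table::data.table(r = rep(seq_len(nrow(ref)), nrow(off)))
  rb$bk <- unlist(lapply(seq_len(nrow(off)), function(k)
    paste(floor(ref[, 1] / hbin) + off[k, 1], floor(ref[, 2] / hbin) + off[k, 2],
          floor(ref[, 3] / hbin) + off[k, 3])))
  qb <- data.table::data.table(q = seq_len(nq), bk = key3(query))
  cand <- rb[qb, on = "bk", allow.cartesian = TRUE, nomatch = NULL]
  out <- integer(nq)
  if (nrow(cand)) {
    d2 <- rowSums((ref[cand$r, , drop = FALSE] -
                     query[cand$q, , drop = FALSE])^2)
    dt <- data.table::data.table(q = cand$q, r = cand$r, d2 = d2)
    best <- dt[, list(r = r[which.min(d2)]), by = "q"]
    out[best$q] <- best$r
  }
  miss <- which(out == 0L)
  for (q in miss) {  # rare fallback: brute force
    out[q] <- which.min(rowSums(sweep(ref, 2, query[q, ])^2))
  }
  out
}

# conforming longest-edge bisection: halve cells incident to wall nodes until
# their volume is at most (initial volume / factor); every cell sharing a
# split edge is bisected across that same edge, keeping the mesh conforming
refine_near_wall <- function(verts, tets, wall_nodes, factor) {
  target <- stats::median(abs(tet_vol(verts, tets))) / factor
  is_wall <- rep(FALSE, nrow(verts))
  is_wall[wall_nodes] <- TRUE
  for (pass in 1:12) {
    vol <- abs(tet_vol(verts, tets))
    touches <- matrix(is_wall[tets], nrow(tets), 4)
    marked <- which(rowSums(touches) > 0 & vol > target * (1 + 1e-9))
    if (!length(marked)) break
    # longest edge of each marked cell
    ep <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    el <- sapply(seq_len(6), function(k)
      rowSums((verts[tets[marked, ep[k, 1]], , drop = FALSE] -
                 verts[tets[marked, ep[k, 2]], , drop = FALSE])^2))
    if (length(marked) == 1L) el <- matrix(el, 1)
    lk <- max.col(el, ties.method = "first")
    ea <- tets[cbind(marked, ep[lk, 1])]
    eb <- tets[cbind(marked, ep[lk, 2])]
    ekey <- paste(pmin(ea, eb), pmax(ea, eb))
    sel_edges <- unique(data.table::data.table(a = pmin(ea, eb),
                                               b = pmax(ea, eb), bk = ekey),
                        by = "bk")
    # greedy independent set: no tet may contain two selected edges
    inc <- cell_edge_incidence(tets, sel_edges)
    ord <- order(sel_edges$bk)  # deterministic
    tet_hit <- rep(FALSE, nrow(tets))
    pick <- logical(nrow(sel_edges))
    for (e in ord) {
      cl <- inc[[e]]
      if (!any(tet_hit[cl])) { pick[e] <- TRUE; tet_hit[cl] <- TRUE }
    }
    sel <- sel_edges[pick]
    inc <- inc[pick]
    # split: add midpoints, bisect every incident tet across its edge
    mid <- (verts[sel$a, , drop = FALSE] + verts[sel$b, , drop = FALSE]) / 2
    mid_id <- nrow(verts) + seq_len(nrow(sel))
    verts <- rbind(verts, mid)
    is_wall <- c(is_wall, is_wall[sel$a] & is_wall[sel$b])
    split_tet <- unlist(inc)
    split_edge <- rep(seq_len(nrow(sel)), lengths(inc))
    old <- tets[split_tet, , drop = FALSE]
    a <- sel$a[split_edge]; b <- sel$b[split_edge]; m <- mid_id[split_edge]
    t1 <- old; t2 <- old
    for (c_ in 1:4) {
      hit_b <- old[, c_] == b
      t1[hit_b, c_] <- m[hit_b]
      hit_a <- old[, c_] == a
      t2[hit_a, c_] <- m[hit_a]
    }
    tets <- rbind(tets[-split_tet, , drop = FALSE], t1, t2)
  }
  list(vertices = verts, cells = tets)
}

tet_vol <- function(verts, tets) {
  p0 <- verts[tets[, 1], , drop = FALSE]
  rowSums((verts[tets[, 2], , drop = FALSE] - p0) *
            cross3(verts[tets[, 3], , drop = FALSE] - p0,
                   verts[tets[, 4], , drop = FALSE] - p0)) / 6
}

# list: per selected edge, the cells containing it
cell_edge_incidence <- function(tets, sel_edges) {
  ep <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ta <- c(); tb <- c(); tc <- c()
  for (k in seq_len(6)) {
    ta <- c(ta, pmin(tets[, ep[k, 1]], tets[, ep[k, 2]]))
    tb <- c(tb, pmax(tets[, ep[k, 1]], tets[, ep[k, 2]]))
    tc <- c(tc, seq_len(nrow(tets)))
  }
  dt <- data.table::data.table(bk = paste(ta, tb), cell = tc)
  dt <- dt[dt$bk %in% sel_edges$bk]
  sp <- split(dt$cell, dt$bk)
  lapply(sel_edges$bk, function(k) sp[[k]])
}

#' Tag a porous layer along the wall of a volume mesh
#'
#' Marks cells whose centroid lies within `thickness` of any wall-tagged
#' boundary face (exact point-to-triangle distance) as `porous`. Cells beyond
#' the basal plane (inside the flow-development tubes) are never tagged when
#' the mesh carries `base_plane` metadata.
#'
#' @param mesh `volume_mesh`
#' @param thickness layer thickness, m
#' @return `volume_mesh` with updated `cell_region`
#' @export
tag_porous_layer <- function(mesh, thickness) {
  check_number(thickness, "thickness", 0)
  out <- mesh
  out$cell_region <- rep("fluid", nrow(mesh$cells))
  if (thickness == 0) return(out)
  wall <- mesh$boundary_faces[mesh$boundary_tags == "wall", , drop = FALSE]
  if (!nrow(wall))
    stop_vf("mesh has no wall-tagged boundary faces",
            class = "ventriflow_mesh_error")
  ctr <- cell_centroids(mesh)
  porous <- within_distance_of_faces(mesh$vertices, wall, ctr, thickness)
  bp <- attr(mesh, "base_plane")
  if (!is.null(bp)) {
    height <- as.vector(sweep(ctr, 2, bp$point) %*% bp$normal)
    porous <- porous & height < 0
  }
  out$cell_region[porous] <- "porous"
  out
}

# which query points lie within `cutoff` of a triangle set; a blockwise
# centroid-distance pass classifies certain points, and only points whose
# centroid distance is within one face circumradius of the cutoff get exact
# point-triangle distances
within_distance_of_faces <- function(verts, faces, query, cutoff) {
  fc <- (verts[faces[, 1], , drop = FALSE] + verts[faces[, 2], , drop = FALSE] +
           verts[faces[, 3], , drop = FALSE]) / 3
  frmax <- sqrt(max(rowSums((verts[faces[, 1], , drop = FALSE] - fc)^2),
                    rowSums((verts[faces[, 2], , drop = FALSE] - fc)^2),
                    rowSums((verts[faces[, 3], , drop = FALSE] - fc)^2)))
  nq <- nrow(query)
  fc2 <- rowSums(fc * fc)
  dcent <- numeric(nq)
  for (blk in split(seq_len(nq), ceiling(seq_len(nq) / 2000))) {
    qb <- query[blk, , drop = FALSE]
    d2 <- matrix(rowSums(qb * qb), length(blk), nrow(fc)) +
      matrix(fc2, length(blk), nrow(fc), byrow = TRUE) - 2 * qb %*% t(fc)
    dcent[blk] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  res <- dcent <= cutoff - frmax
  band <- which(dcent > cutoff - frmax & dcent <= cutoff + frmax)
  for (blk in split(band, ceiling(seq_along(band) / 500))) {
    qb <- query[blk, , drop = FALSE]
    d2 <- matrix(rowSums(qb * qb), length(blk), nrow(fc)) +
      matrix(fc2, length(blk), nrow(fc), byrow = TRUE) - 2 * qb %*% t(fc)
    pair <- which(d2 <= (cutoff + 2 * frmax)^2, arr.ind = TRUE)
    if (!nrow(pair)) next
    qi <- blk[pair[, 1]]; fi <- pair[, 2]
    d <- point_triangle_distance(query[qi, , drop = FALSE],
                                 verts[faces[fi, 1], , drop = FALSE],
                                 verts[faces[fi, 2], , drop = FALSE],
                                 verts[faces[fi, 3], , drop = FALSE])
    ok <- d <= cutoff
    res[unique(qi[ok])] <- TRUE
  }
  res
}

# exact (vectorized) point-triangle distance (Eberly-style region reduction
# via clamped barycentric projection onto the plane, then edge clamping)
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  res <- rep(NA_real_, nrow(p))

  reg <- d1 <= 0 & d2 <= 0                       # vertex a
  res[reg] <- rowSums(ap[reg, , drop = FALSE]^2)
  reg2 <- is.na(res) & d3 >= 0 & d4 <= d3        # vertex b
  res[reg2] <- rowSums(bp[reg2, , drop = FALSE]^2)
  reg3 <- is.na(res) & d6 >= 0 & d5 <= d6        # vertex c
  res[reg3] <- rowSums(cp[reg3, , drop = FALSE]^2)
  reg4 <- is.na(res) & vc <= 0 & d1 >= 0 & d3 <= 0  # edge ab
  if (any(reg4)) {
    v <- d1[reg4] / (d1[reg4] - d3[reg4])
    q <- a[reg4, , drop = FALSE] + v * ab[reg4, , drop = FALSE]
    res[reg4] <- rowSums((p[reg4, , drop = FALSE] - q)^2)
  }
  reg5 <- is.na(res) & vb <= 0 & d2 >= 0 & d6 <= 0  # edge ac
  if (any(reg5)) {
    v <- d2[reg5] / (d2[reg5] - d6[reg5])
    q <- a[reg5, , drop = FALSE] + v * ac[reg5, , drop = FALSE]
    res[reg5] <- rowSums((p[reg5, , drop = FALSE] - q)^2)
  }
  reg6 <- is.na(res) & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge bc
  if (any(reg6)) {
    v <- (d4[reg6] - d3[reg6]) / ((d4[reg6] - d3[reg6]) + (d5[reg6] - d6[reg6]))
    q <- b[reg6, , drop = FALSE] +
      v * (c[reg6, , drop = FALSE] - b[reg6, , drop = FALSE])
    res[reg6] <- rowSums((p[reg6, , drop = FALSE] - q)^2)
  }
  rem <- is.na(res)                               # interior
  if (any(rem)) {
    den <- va[rem] + vb[rem] + vc[rem]
    v <- vb[rem] / den; w <- vc[rem] / den
    q <- a[rem, , drop = FALSE] + v * ab[rem, , drop = FALSE] +
      w * ac[rem, , drop = FALSE]
    res[rem] <- rowSums((p[rem, , drop = FALSE] - q)^2)
  }
  sqrt(pmax(res, 0))
}
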