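# Equal-order P1 finite-element core, dimension-agnostic (triangles in 2D,
# tetrahedra in 3D). Velocity and kinematic pressure share the nodal space;
# the pressure projection uses the compatible discrete operators
#   B_d = SV G_d   (weak derivative:  (B_d f)_i = int phi_i d f/dx_d)
# so that the projected velocity satisfies the weak divergence constraint at
# every free pressure node to solver precision.

#' Build the P1 finite-element structure for a simplex mesh
#'
#' @param vertices n x d node coordinates (d = 2 or 3)
#' @param cells m x (d+1) simplex connectivity
#' @param fold optional length-n index map folding periodic duplicate nodes
#'   onto their representatives (identity entries for interior nodes)
#' @return `fem_structure` list with cell volumes, basis gradients, lumped
#'   mass, weak-derivative matrices `B[[d]]` and the stiffness matrix `L`
#' @export
build_fem <- function(vertices, cells, fold = NULL) {
  vertices <- as.matrix(vertices)
  cells <- as.matrix(cells)
  d <- ncol(vertices)
  if (!d %in% c(2L, 3L)) stop_vf("only 2D and 3D meshes are supported")
  if (ncol(cells) != d + 1L) stop_vf("cells must be m x (d+1)")
  nv_geo <- nrow(vertices)
  if (is.null(fold)) fold <- seq_len(nv_geo)
  rep_ids <- sort(unique(fold))
  renum <- match(fold, rep_ids)          # geometric node -> dof index
  nv <- length(rep_ids)
  cells_dof <- matrix(renum[cells], nrow(cells))

  nc <- nrow(cells)
  p0 <- vertices[cells[, 1], , drop = FALSE]
  E <- lapply(seq_len(d), function(k)
    vertices[cells[, k + 1L], , drop = FALSE] - p0)  # edge vectors
  if (d == 2L) {
    det <- E[[1]][, 1] * E[[2]][, 2] - E[[1]][, 2] * E[[2]][, 1]
    vol <- abs(det) / 2
    # rows of the inverse Jacobian: grad of barycentric coords 2..d+1
    gb <- list(cbind(E[[2]][, 2], -E[[2]][, 1]) / det,
               cbind(-E[[1]][, 2], E[[1]][, 1]) / det)
  } else {
    c23 <- cross3(E[[2]], E[[3]]); c31 <- cross3(E[[3]], E[[1]])
    c12 <- cross3(E[[1]], E[[2]])
    det <- rowSums(E[[1]] * c23)
    vol <- abs(det) / 6
    gb <- list(c23 / det, c31 / det, c12 / det)
  }
  if (any(vol <= 0) || any(!is.finite(det)))
    stop_vf("degenerate cell in mesh", class = "ventriflow_mesh_error")
  # minimum cell height d*V/A_max (time-step estimation), from true geometry
  if (d == 2L) {
    e3 <- E[[2]] - E[[1]]
    amax <- pmax(rowSums(E[[1]]^2), rowSums(E[[2]]^2), rowSums(e3^2))
    h_cell <- 2 * vol / sqrt(amax)
  } else {
    amax <- pmax(row_norms(c23), row_norms(c31), row_norms(c12),
                 row_norms(cross3(E[[2]] - E[[1]], E[[3]] - E[[1]])))
    h_cell <- 6 * vol / amax
  }
  # grad coefficients: G[[k]][, l] = d phi_l / dx_k on each cell
  G <- lapply(seq_len(d), function(k) {
    g <- matrix(0, nc, d + 1L)
    for (l in seq_len(d)) g[, l + 1L] <- gb[[l]][, k]
    g[, 1L] <- -rowSums(g[, -1L, drop = FALSE])
    g
  })

  m <- numeric(nv)
  for (l in seq_len(d + 1L))
    m <- m + scatter_add(cells_dof[, l], vol / (d + 1), nv)

  ii <- as.vector(cells_dof)
  cc <- rep(seq_len(nc), d + 1L)
  SV <- Matrix::sparseMatrix(i = ii, j = cc, x = rep(vol / (d + 1), d + 1L),
                             dims = c(nv, nc))
  B <- vector("list", d)
  L <- NULL
  for (k in seq_len(d)) {
    Gk <- Matrix::sparseMatrix(i = cc, j = ii, x = as.vector(G[[k]]),
                               dims = c(nc, nv))
    B[[k]] <- SV %*% Gk
    Lk <- Matrix::t(Gk) %*% (vol * Gk)
    L <- if (is.null(L)) Lk else L + Lk
  }
  structure(list(d = d, nv = nv, nc = nc, cells = cells_dof, vol = vol,
                 G = G, m = m, B = B, L = L, renum = renum, h_cell = h_cell,
                 vertices = vertices[match(seq_len(nv), renum), , drop = FALSE]),
            class = "fem_structure")
}

# cell-wise derivative d f / dx_k of a nodal field (length-nc vector)
cell_deriv <- function(fem, f, k) {
  g <- fem$G[[k]]
  out <- numeric(fem$nc)
  for (l in seq_len(fem$d + 1L))
    out <- out + g[, l] * f[fem$cells[, l]]
  out
}

# cell averages of a nodal field
cell_mean <- function(fem, f) {
  out <- numeric(fem$nc)
  for (l in seq_len(fem$d + 1L)) out <- out + f[fem$cells[, l]]
  out / (fem$d + 1)
}

#' Weak-form nonlinear term of the momentum equation
#'
#' Assembles the nodal force `int phi_i NL(u)` with exact quadrature (the
#' integrand is the product of a cell-constant velocity-gradient combination
#' and the linear velocity). Forms: `CONV` is `u . grad u`; `EMAC` is
#' `2 S(u) u + (div u) u` with `S` the symmetric gradient.
#'
#' @param fem `fem_structure`
#' @param u nodal velocity matrix (nv x d)
#' @param form `"CONV"` or `"EMAC"`
#' @return nodal force matrix (nv x d)
#' @export
assemble_nonlinear <- function(fem, u, form = c("EMAC", "CONV")) {
  form <- match.arg(form)
  d <- fem$d; np <- d + 1L
  du <- vector("list", d)  # du[[a]][[k]] = d u_a / dx_k per cell
  for (a in seq_len(d))
    du[[a]] <- lapply(seq_len(d), function(k) cell_deriv(fem, u[, a], k))
  A <- vector("list", d)   # A[[a]][[k]]: NL(u)_a = sum_k A_ak u_k (per cell)
  if (form == "CONV") {
    for (a in seq_len(d)) A[[a]] <- du[[a]]
  } else {
    divu <- du[[1]][[1]]
    for (k in 2:d) divu <- divu + du[[k]][[k]]
    for (a in seq_len(d))
      A[[a]] <- lapply(seq_len(d), function(k)
        du[[a]][[k]] + du[[k]][[a]] + if (a == k) divu else 0)
  }
  Ucell <- lapply(seq_len(d), function(k) {
    s <- matrix(0, fem$nc, np)
    for (l in seq_len(np)) s[, l] <- u[fem$cells[, l], k]
    s
  })
  Usum <- lapply(Ucell, rowSums)
  w <- fem$vol / (np * (np + 1))
  out <- matrix(0, fem$nv, d)
  for (i in seq_len(np)) {
    node <- fem$cells[, i]
    for (a in seq_len(d)) {
      acc <- numeric(fem$nc)
      for (k in seq_len(d))
        acc <- acc + A[[a]][[k]] * (Usum[[k]] + Ucell[[k]][, i])
      out[, a] <- out[, a] + scatter_add(node, w * acc, fem$nv)
    }
  }
  out
}

#' Kinetic energy of a nodal velocity field
#'
#' `0.5 int |u|^2` with the exact quadrature for products of linears
#' (consistent mass), or `0.5 u' M_L u` with the lumped mass. The lumped
#' energy is the quantity the discrete dynamics conserve exactly: the EMAC
#' momentum term satisfies `u' N(u) = 0` and the pressure projection is
#' orthogonal in the lumped inner product.
#'
#' @param fem `fem_structure`
#' @param u nodal velocity (nv x d)
#' @param lumped use the lumped mass matrix
#' @return energy (per unit density), m^(2+d)/s^2
#' @export
kinetic_energy <- function(fem, u, lumped = FALSE) {
  if (lumped) return(sum(fem$m * rowSums(u^2)) / 2)
  d <- fem$d; np <- d + 1L
  w <- fem$vol / (np * (np + 1))
  e <- 0
  for (k in seq_len(d)) {
    Uc <- matrix(0, fem$nc, np)
    for (l in seq_len(np)) Uc[, l] <- u[fem$cells[, l], k]
    s <- rowSums(Uc)
    e <- e + sum(w * (s^2 + rowSums(Uc^2)))
  }
  e / 2
}

#' Weak divergence of a nodal velocity field
#' @param fem `fem_structure`
#' @param u nodal velocity (nv x d)
#' @return nodal vector `int phi_i div u`
#' @export
weak_divergence <- function(fem, u) {
  out <- numeric(fem$nv)
  for (k in seq_len(fem$d)) out <- out + as.vector(fem$B[[k]] %*% u[, k])
  out
}
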