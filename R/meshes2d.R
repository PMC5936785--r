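# Structured 2D triangle meshes for solver validation: a periodic square
# (Taylor-Green) and an x-periodic channel (Poiseuille). Periodicity is
# expressed through a fold map consumed by [build_fem()].

#' Structured triangulated rectangle
#'
#' Splits an `nx` x `ny` grid of quads over `[0,Lx] x [0,Ly]` into two
#' triangles each (consistent diagonal).
#'
#' @param nx,ny number of cells per direction
#' @param Lx,Ly side lengths
#' @return list with `vertices` (n x 2), `cells` (m x 3) and the grid index
#'   helper `nid(i, j)`
#' @export
rect_grid2d <- function(nx, ny, Lx = 1, Ly = 1) {
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  vertices <- as.matrix(expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE))
  nid <- function(i, j) i + (j - 1L) * (nx + 1L)
  ij <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny)))
  a <- nid(ij[, 1], ij[, 2]);     b <- nid(ij[, 1] + 1L, ij[, 2])
  c_ <- nid(ij[, 1] + 1L, ij[, 2] + 1L); d <- nid(ij[, 1], ij[, 2] + 1L)
  cells <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  list(vertices = vertices, cells = cells, nid = nid, nx = nx, ny = ny,
       Lx = Lx, Ly = Ly)
}

#' Fold map identifying periodic boundary nodes of a rectangular grid
#'
#' @param grid result of [rect_grid2d()]
#' @param periodic_x,periodic_y identify the right/top boundary with the
#'   left/bottom one
#' @return integer fold map usable as `fold` in [build_fem()]
#' @export
periodic_fold2d <- function(grid, periodic_x = TRUE, periodic_y = TRUE) {
  n <- nrow(grid$vertices)
  fold <- seq_len(n)
  nx <- grid$nx; ny <- grid$ny
  if (periodic_x)
    for (j in seq_len(ny + 1L)) fold[grid$nid(nx + 1L, j)] <- grid$nid(1L, j)
  if (periodic_y)
    for (i in seq_len(nx + 1L)) fold[grid$nid(i, ny + 1L)] <- fold[grid$nid(i, 1L)]
  fold
}

#' Taylor-Green vortex velocity field
#'
#' `u = ( sin x cos y, -cos x sin y ) exp(-2 nu t)` on the `2 pi` periodic
#' square; kinetic energy decays as `exp(-4 nu t)`.
#'
#' @param xy n x 2 coordinates
#' @param t time, s
#' @param nu kinematic viscosity
#' @return n x 2 velocity
#' @export
taylor_green <- function(xy, t = 0, nu = 0) {
  decay <- exp(-2 * nu * t)
  cbind(sin(xy[, 1]) * cos(xy[, 2]), -cos(xy[, 1]) * sin(xy[, 2])) * decay
}
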