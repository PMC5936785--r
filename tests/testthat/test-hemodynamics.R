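test_that("Freedman-Diaconis histogram matches its oracle and normalizes", {
  set.seed(7)
  x <- runif(1000)
  h <- fd_histogram(x)
  expect_equal(h$bin_width, 2 * IQR(x, type = 7) * length(x)^(-1 / 3))
  expect_equal(sum(h$density * h$bin_width), 1)
  # mode of a stratified Gaussian sample sits within one bin of the true mode
  g <- fd_histogram(qnorm(((1:1e5) - 0.5) / 1e5, mean = 5))
  expect_lt(abs(g$mode_value - 5), g$bin_width)
  # zero-IQR degenerate sample falls back to a single bin at the value
  cz <- fd_histogram(rep(3.3, 10))
  expect_equal(cz$mode_value, 3.3)
  expect_equal(sum(cz$density * cz$bin_width), 1)
})

test_that("mode-based pressure drop is shift-invariant and in kPa", {
  set.seed(1)
  base <- rnorm(200, sd = 50)
  mk_run <- function(shift) {
    frames <- lapply(1:12, function(i)
      list(p_in = base + 10500 + shift, p_out = base + 10000 + shift))
    list(probe_frames = frames)
  }
  d0 <- pressure_drop(mk_run(0))
  d1 <- pressure_drop(mk_run(12345))
  expect_equal(d0$delta_p, 0.5)        # kPa
  expect_equal(d0$delta_p_sd, 0)       # identical frames
  expect_equal(d1$delta_p, d0$delta_p) # gauge shift drops out
})

test_that("Q-criterion closed forms hold at interior cells", {
  mesh <- box_mesh(c(4, 4, 4), 1)
  fem <- build_fem(mesh$vertices, mesh$cells)
  v <- fem$vertices
  om <- 3; ga <- 2
  urot <- cbind(-om * v[, 2], om * v[, 1], 0)
  expect_lt(max(abs(q_criterion(fem, urot) - om^2)), 1e-10)
  expect_lt(max(abs(q_criterion(fem, cbind(ga * v[, 2], 0 * v[, 1], 0)))),
            1e-10)
  expect_lt(max(abs(q_criterion(fem, cbind(ga * v[, 1], -ga * v[, 2], 0)) +
                      ga^2)), 1e-10)
  # Galilean invariance
  ug <- urot + matrix(c(1, 2, 3), fem$nv, 3, byrow = TRUE)
  expect_equal(q_criterion(fem, ug), q_criterion(fem, urot))
})

test_that("wall shear stress vanishes for rigid motions and uniform flow", {
  chan <- box_mesh(c(2, 8, 2), c(0.5, 1, 0.5))
  fem <- build_fem(chan$vertices, chan$cells)
  v <- fem$vertices
  wr <- wall_shear_stress(fem, cbind(-3 * v[, 2], 3 * v[, 1], 0), chan)
  expect_lt(max(wr$wss), 1e-10)
  wu <- wall_shear_stress(fem, matrix(c(0.3, 0.1, -0.2), fem$nv, 3,
                                      byrow = TRUE), chan)
  expect_lt(max(wu$wss), 1e-12)
})

test_that("vortex surface is monotone in the threshold and empty beyond max Q", {
  bm <- box_mesh(12, 1)
  fem <- build_fem(bm$vertices, bm$cells)
  ctr <- cell_centroids(bm)
  r <- sqrt(rowSums(sweep(ctr, 2, c(0.5, 0.5, 0.5))^2))
  qc <- 1000 * (1 - r / 0.4)
  a1 <- vortex_surface(fem, qc, 500)
  a2 <- vortex_surface(fem, qc, 750)
  expect_gt(a1, 0)
  expect_lte(a2, a1)
  expect_equal(vortex_surface(fem, qc, 2000), 0)
})
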