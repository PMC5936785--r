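test_that("box_mesh partitions the box exactly with positive cells", {
  bm <- box_mesh(c(3, 2, 4), c(0.3, 0.2, 0.4))
  vols <- cell_volumes(bm)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 0.3 * 0.2 * 0.4)
  expect_identical(unique(bm$boundary_tags), "wall")
  # boundary faces tile the box surface
  v0 <- bm$vertices[bm$boundary_faces[, 1], , drop = FALSE]
  n <- cross3_area2(bm$vertices[bm$boundary_faces[, 2], , drop = FALSE] - v0,
                    bm$vertices[bm$boundary_faces[, 3], , drop = FALSE] - v0)
  expect_equal(sum(sqrt(rowSums(n^2))) / 2,
               2 * (0.3 * 0.2 + 0.2 * 0.4 + 0.3 * 0.4))
})

test_that("cavity tetrahedralization is tagged, positive, and inside the band", {
  mesh <- fx_mesh()
  vols <- cell_volumes(mesh)
  expect_true(all(vols > 0))
  # warping boundary lattice nodes onto the surface can inflate a near-wall
  # cell slightly past the lattice bound
  expect_lte(max(vols), (0.006)^3 / 6 * 1.25)
  expect_setequal(unique(mesh$boundary_tags), c("wall", "inlet", "outlet"))
  expect_identical(unique(mesh$cell_region), "fluid")
  # every boundary face belongs to exactly one cell (closed boundary)
  expect_identical(anyDuplicated(apply(mesh$boundary_faces, 1,
                                       function(f) paste(sort(f), collapse = "-"))),
                   0L)
  # total boundary area is close to the source surface area
  sa <- sum(face_areas(fx_surface()))
  v0 <- mesh$vertices[mesh$boundary_faces[, 1], , drop = FALSE]
  n <- cross3_area2(mesh$vertices[mesh$boundary_faces[, 2], , drop = FALSE] - v0,
                    mesh$vertices[mesh$boundary_faces[, 3], , drop = FALSE] - v0)
  ba <- sum(sqrt(rowSums(n^2))) / 2
  # a staircase boundary always exceeds the smooth area it approximates
  # (an axis-aligned staircase of a tilted plane can carry up to ~sqrt(3)
  # times the area), but stays well under doubling it
  expect_gt(ba / sa, 1)
  expect_lt(ba / sa, 2)
})

test_that("invalid meshing parameters are rejected", {
  expect_error(tetrahedralize(fx_surface(), max_cell_volume = 0),
               class = "ventriflow_validation_error")
  expect_error(tetrahedralize(fx_surface(), max_cell_volume = 1e-8,
                              jitter = 0.5),
               class = "ventriflow_validation_error")
  expect_error(box_mesh(0), class = "ventriflow_validation_error")
})
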