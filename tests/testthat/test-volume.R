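test_that("signed tetrahedron volume matches the determinant expansion", {
  expect_equal(signed_tet_volume(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1 / 6)
  expect_equal(signed_tet_volume(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)), -1 / 6)
  expect_equal(signed_tet_volume(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)), 0)
  set.seed(9)
  for (i in 1:100) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    expect_equal(signed_tet_volume(a, b, c), tet_volume_expansion(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("unit cube volume is exact and origin-independent", {
  cube <- unit_cube_mesh()
  v <- mesh_volume(cube)
  expect_equal(v$volume, 1, tolerance = 1e-12)
  expect_equal(v$facet_count, 12L)
  shifted <- triangle_mesh(sweep(cube$vertices, 2, c(-100, 50, -3)),
                           cube$faces)
  expect_equal(mesh_volume(shifted)$volume, 1, tolerance = 1e-12)
  # origin invariance at 1e-10 relative: (0,0,0), centroid, far point
  for (o in list(c(0, 0, 0), colMeans(cube$vertices), c(1e3, -2e3, 5e2))) {
    expect_equal(mesh_volume(cube, origin = o)$volume, 1, tolerance = 1e-10)
  }
})

test_that("winding flips leave the absolute volume unchanged", {
  for (mesh in list(unit_cube_mesh(), icosphere_mesh(2))) {
    v1 <- mesh_volume(mesh)
    flipped <- triangle_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)])
    v2 <- mesh_volume(flipped)
    expect_equal(v2$volume, v1$volume, tolerance = 1e-12)
  }
})

test_that("orient_faces repairs inconsistent windings", {
  cube <- unit_cube_mesh()
  broken <- cube
  broken$faces[5, ] <- broken$faces[5, c(1, 3, 2)]
  fixed <- orient_faces(broken)
  sv <- cloudvol:::mesh_signed_volume(fixed)
  expect_equal(abs(sv), 1, tolerance = 1e-12)
  expect_gt(sv, 0)  # default sign: positive signed volume
  # already-consistent mesh is a fixed point
  ico <- icosphere_mesh(1)
  ico <- orient_faces(ico)
  expect_equal(orient_faces(ico)$faces, ico$faces)
  # non-watertight input is rejected
  expect_error(orient_faces(triangle_mesh(cube$vertices, cube$faces[-1, ])),
               "not watertight")
  expect_error(mesh_volume(triangle_mesh(cube$vertices, cube$faces[-1, ])),
               "open")
})

test_that("a reference cloud with inward normals selects inward facet normals", {
  cube <- unit_cube_mesh()
  sh <- sample_shape(shape_spec("cube", density = 400))
  P <- sh$cloud$points
  ctr <- c(0.5, 0.5, 0.5)
  inward <- sweep(-sweep(P, 2, ctr), 1,
                  sqrt(rowSums(sweep(P, 2, ctr)^2)), "/")
  ref <- point_cloud(P, normals = inward)
  m_in <- orient_faces(cube, reference = ref)
  expect_lt(cloudvol:::mesh_signed_volume(m_in), 0)  # inward winding
  expect_equal(abs(cloudvol:::mesh_signed_volume(m_in)), 1, tolerance = 1e-12)
})

test_that("icosphere volume agrees with the analytic value and the voxel oracle", {
  ico <- icosphere_mesh(4)
  v <- mesh_volume(ico)
  expect_lt(abs(v$volume - 4 * pi / 3) / (4 * pi / 3), 0.005)
  vox <- voxel_volume(ico, 256)
  expect_lt(abs(v$volume - vox) / vox, 0.005)
})

test_that("voxel oracle agrees on cube, cylinder and piglet fixtures", {
  expect_equal(voxel_volume(unit_cube_mesh(), 128), 1, tolerance = 0.005)
  cyl <- cylinder_mesh(nseg = 256)
  expect_equal(voxel_volume(cyl, 256) / mesh_volume(cyl)$volume, 1,
               tolerance = 0.005)
  pig <- piglet_mesh(96)
  expect_equal(voxel_volume(pig, 256) / mesh_volume(pig)$volume, 1,
               tolerance = 0.005)
})

test_that("slicing volume is accurate on convex fixtures", {
  cube <- sample_shape(shape_spec("cube", density = 1e4))
  v <- slicing_volume(cube$cloud, axis = "z", interval = 0.02)
  expect_lt(abs(v$volume - 1), 0.01)
  cyl <- sample_shape(shape_spec("cylinder", density = 3000))
  vc <- slicing_volume(cyl$cloud, axis = "z", interval = 0.02)
  expect_lt(abs(vc$volume - pi) / pi, 0.01)
  expect_equal(v$method, "slicing")
})

test_that("slicing strictly overestimates the concave L-prism", {
  lp <- sample_shape(shape_spec("l_prism", density = 1e4))
  v <- slicing_volume(lp$cloud, axis = "z", interval = 0.02)
  expect_gt(v$volume, lp$volume)           # convex hull inflates the L
  expect_lt(abs(v$volume - 0.875) / 0.875, 0.02)  # hull cross-section area
  # the tetrahedral route on a reconstructed mesh does not share the bias
  mesh <- reconstruct(lp$cloud, depth = 6)
  expect_lt(abs(mesh_volume(mesh)$volume - lp$volume) / lp$volume, 0.01)
})

test_that("min_point_spacing matches the brute-force pairwise minimum", {
  g <- as.matrix(expand.grid(seq(0, 0.1, 0.01), seq(0, 0.1, 0.01), 0))
  expect_equal(min_point_spacing(point_cloud(g)), 0.01, tolerance = 1e-12)
  two <- point_cloud(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(min_point_spacing(two), 5)
  set.seed(13)
  P <- matrix(runif(3000), ncol = 3)
  d <- as.matrix(dist(P))
  diag(d) <- Inf
  expect_equal(min_point_spacing(point_cloud(P)), min(d), tolerance = 1e-12)
})
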