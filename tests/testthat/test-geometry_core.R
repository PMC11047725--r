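test_that("point_cloud and triangle_mesh enforce their invariants", {
  expect_error(point_cloud(matrix(numeric(0), 0, 3)), "at least one point")
  expect_error(point_cloud(rbind(c(0, 0, NA))), "finite")
  expect_error(point_cloud(rbind(c(0, 0, 0)), normals = rbind(c(0, 0, 0))),
               "zero-norm")
  cl <- point_cloud(rbind(c(0, 0, 0)), normals = rbind(c(0, 0, 2)))
  expect_equal(sqrt(sum(cl$normals^2)), 1, tolerance = 1e-12)
  expect_error(point_cloud(rbind(c(0, 0, 0)), confidence = 1.5), "\\[0, 1\\]")
  m <- unit_cube_mesh()
  expect_error(triangle_mesh(m$vertices, rbind(c(1, 2, 13))), "out of range")
  expect_error(triangle_mesh(m$vertices, rbind(c(1, 2, 2))), "repeated")
})

test_that("XYZ parsing handles plain and normal-bearing records", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0", "0 1 0"), path)
  cl <- read_point_cloud(path)
  expect_equal(n_points(cl), 3L)
  expect_null(cl$normals)
  expect_equal(cl$points[2, ], c(1, 0, 0))
  writeLines(c("0 0 0 0 0 3", "1 0 0 2 0 0"), path)
  cl <- read_point_cloud(path, "xyz")
  expect_equal(cl$normals, rbind(c(0, 0, 1), c(1, 0, 0)))
  writeLines(c("0 0 0", "1 oops 0"), path)
  expect_error(read_point_cloud(path, "xyz"), "line 2")
})

test_that("point-cloud round-trips are lossless to declared precision", {
  set.seed(42)
  cl <- point_cloud(matrix(runif(3e4, -5, 5), ncol = 3))
  for (fmt in c("xyz", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_point_cloud(cl, path)
    back <- read_point_cloud(path)
    expect_lt(max(abs(back$points - cl$points)), 1e-5)
  }
  # with normals through binary little-endian PLY (float32 precision)
  n <- matrix(rnorm(300), ncol = 3)
  cln <- point_cloud(matrix(runif(300), ncol = 3), normals = n)
  path <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(cln, path, "ply", binary = TRUE)
  back <- read_point_cloud(path)
  expect_lt(max(abs(back$points - cln$points)), 1e-6)
  expect_lt(max(abs(back$normals - cln$normals)), 1e-6)
  expect_equal(sqrt(rowSums(back$normals^2)), rep(1, 100), tolerance = 1e-6)
})

test_that("mesh I/O preserves faces and orientation across PLY and OBJ", {
  cube <- unit_cube_mesh()
  sv0 <- cloudvol:::mesh_signed_volume(cube)
  for (fmt in c("ply", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(cube, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$vertices), 8L)
    expect_equal(nrow(back$faces), 12L)
    expect_equal(cloudvol:::mesh_signed_volume(back), sv0, tolerance = 1e-9)
  }
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(cube, path, binary = TRUE)
  expect_equal(read_mesh(path)$faces, cube$faces)
})

test_that("OBJ quads are fan-split and larger polygons rejected", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), path)
  m <- read_mesh(path)
  expect_equal(m$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "v 0 2 0",
               "f 1 2 3 4 5"), path)
  expect_error(read_mesh(path), "triangles and quads")
})

test_that("watertight predicate distinguishes closed and holed meshes", {
  cube <- unit_cube_mesh()
  expect_true(is_watertight(cube))
  holed <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  wt <- is_watertight(holed)
  expect_false(as.logical(wt))
  expect_equal(attr(wt, "open_edges"), 3L)
  ico <- icosphere_mesh(2)
  expect_true(is_watertight(ico))
})

test_that("knn is exact, self-excluding and index-tie-broken", {
  # collinear points
  cl <- point_cloud(cbind(0:3, 0, 0))
  nb <- knn(cl, 1)
  expect_equal(nb$idx[2, 1], 1L)  # tie between 1 and 3 -> lower index
  expect_equal(nb$dist[2, 1], 1)
  expect_equal(nb$idx[3, 1], 2L)
  # square with equidistant diagonal-free ties
  sq <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  nb <- knn(sq, 2)
  expect_equal(nb$idx[1, ], c(2L, 3L))  # both at distance 1, ascending index
  expect_error(knn(sq, 4), "smaller than")
})

test_that("knn agrees with the brute-force oracle on random clouds", {
  set.seed(7)
  for (n in c(120L, 500L)) {
    P <- matrix(runif(3 * n), ncol = 3)
    cl <- point_cloud(P)
    k <- 8L
    got <- knn(cl, k)
    want <- brute_knn(P, k)
    expect_equal(got$idx, want$idx)
    expect_equal(got$dist, want$dist, tolerance = 1e-12)
    expect_true(all(diff(t(got$dist)) >= -1e-15))  # ascending distances
    expect_true(all(got$idx != row(got$idx)))      # never lists itself
  }
})
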