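test_that("generators are pure functions of spec and seed", {
  for (kind in c("cube", "sphere", "l_prism")) {
    a <- sample_shape(shape_spec(kind, density = 200, jitter = 0.5, seed = 4))
    b <- sample_shape(shape_spec(kind, density = 200, jitter = 0.5, seed = 4))
    expect_identical(a$cloud$points, b$cloud$points)
  }
  t1 <- make_volume_weight_table(n = 50, seed = 9)
  t2 <- make_volume_weight_table(n = 50, seed = 9)
  expect_identical(t1, t2)
})

test_that("shape samplers deliver the requested density and ground truths", {
  cube <- sample_shape(shape_spec("cube", density = 1e4))
  expect_equal(n_points(cube$cloud), 60000L)  # 6 faces x 100 x 100
  expect_equal(cube$volume, 1)
  cyl <- sample_shape(shape_spec("cylinder"))
  expect_equal(cyl$volume, pi)
  sph <- sample_shape(shape_spec("sphere", density = 500))
  expect_equal(sph$volume, 4 * pi / 3)
  expect_equal(max(abs(sqrt(rowSums(sph$cloud$points^2)) - 1)), 0,
               tolerance = 1e-12)
  lp <- sample_shape(shape_spec("l_prism"))
  expect_equal(lp$volume, 0.75)
  tp <- sample_shape(shape_spec("thin_plate"))
  expect_equal(tp$volume, 0.05)
  expect_error(shape_spec("dodecahedron"), "arg")
})

test_that("the piglet ground truth is self-consistent with the voxel oracle", {
  pig <- sample_shape(shape_spec("piglet", density = 4e3, resolution = 96))
  expect_gt(n_points(pig$cloud), 1000)
  mesh <- piglet_mesh(96)
  expect_true(is_watertight(mesh))
  expect_equal(pig$volume, mesh_volume(mesh)$volume, tolerance = 1e-12)
  expect_equal(voxel_volume(mesh, 256) / pig$volume, 1, tolerance = 0.005)
})

test_that("corrupt applies exactly the requested noise", {
  sh <- sample_shape(shape_spec("sphere", density = 800))
  cl <- point_cloud(sh$cloud$points,
                    normals = sh$cloud$points)  # outward radial
  # identity corruption
  same <- corrupt(cl, noise_spec(), seed = 3)
  expect_identical(same$points, cl$points)
  # exact outlier count
  n <- n_points(cl)
  out <- corrupt(cl, noise_spec(outlier_fraction = 0.01, outlier_scale = 0.5),
                 seed = 3)
  moved <- rowSums(abs(out$points - cl$points)) > 0
  expect_equal(sum(moved), round(0.01 * n))
  # occlusion removes the requested region
  occ <- corrupt(cl, noise_spec(occlusion = occlusion_box(c(-2, -2, 0.5),
                                                          c(2, 2, 2))),
                 seed = 3)
  expect_true(all(occ$points[, 3] < 0.5))
  expect_lt(n_points(occ), n)
})

test_that("reconstruction bridges an occluded piglet leg", {
  pig <- sample_shape(shape_spec("piglet", density = 3e4, resolution = 96))
  full <- reconstruct(pig$cloud, depth = 6)
  v_full <- mesh_volume(full)$volume
  # hide the lower half of one leg (scan shadowed by a railing)
  occ <- noise_spec(occlusion = occlusion_box(c(0.14, 0.03, 0), c(0.26, 0.14, 0.22)))
  occluded <- corrupt(pig$cloud, occ, seed = 1)
  expect_lt(n_points(occluded), n_points(pig$cloud))
  part <- reconstruct(occluded, depth = 6)
  expect_true(is_watertight(part))
  v_part <- mesh_volume(part)$volume
  leg_volume <- pi * 0.04^2 * 0.32 + 2 / 3 * pi * 0.04^3
  expect_lt(abs(v_full - v_part), leg_volume)
})

test_that("volume-weight tables have the calibrated correlation", {
  for (seed in 1:10) {
    tab <- make_volume_weight_table(n = 300, seed = seed)
    m <- fit_weight_model(tab$volume, tab$weight)
    expect_lt(abs(m$r - 0.95), 0.02)
  }
  # noiseless table recovers the generator line exactly
  tab0 <- make_volume_weight_table(n = 50, sigma_kg = 0, seed = 2)
  m0 <- fit_weight_model(tab0$volume, tab0$weight)
  expect_equal(m0$a, 1070.4, tolerance = 1e-9)
  expect_equal(m0$b, -1.6524, tolerance = 1e-9)
})

test_that("tables round-trip through the CSV interface", {
  tab <- make_volume_weight_table(n = 40, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back$volume, tab$volume, tolerance = 1e-10)
  expect_equal(back$weight, tab$weight, tolerance = 1e-10)
})
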