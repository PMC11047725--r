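# Solver-level contracts. Fixtures are kept at depth 5-7 so the whole file
# runs in well under a minute; the depth-8 end-to-end runs live in
# test-acceptance.R.

inward_sphere_cloud <- function(density = 800) {
  sph <- sample_shape(shape_spec("sphere", density = density))
  P <- sph$cloud$points
  point_cloud(P, normals = -P / sqrt(rowSums(P^2)))
}

test_that("zero vector field yields the zero indicator", {
  cl <- inward_sphere_cloud(80)
  tr <- build_octree(cl, 5)
  f0 <- splat_vector_field(tr, cl, weights = rep(0, n_points(cl)))
  ind <- solve_poisson(tr, f0)
  expect_equal(max(abs(ind$chi)), 0)
})

test_that("the solve is linear in the input normals", {
  cl <- inward_sphere_cloud(200)
  tr <- build_octree(cl, 5)
  ind1 <- solve_poisson(tr, splat_vector_field(tr, cl))
  ind2 <- solve_poisson(tr, splat_vector_field(tr, cl,
                                               weights = rep(2, n_points(cl))))
  expect_equal(ind2$chi, 2 * ind1$chi, tolerance = 1e-6)
})

test_that("lambda = 0 and all-tau-zero screened solves equal plain Poisson", {
  cl <- inward_sphere_cloud(200)
  tr <- build_octree(cl, 5)
  f <- splat_vector_field(tr, cl)
  plain <- solve_poisson(tr, f)
  scr0 <- solve_screened_poisson(tr, f, cl, screened_config(lambda = 0, depth = 5))
  expect_equal(scr0$chi, plain$chi, tolerance = 1e-8)
  cl0 <- point_cloud(cl$points, normals = cl$normals,
                     confidence = rep(0, n_points(cl)))
  scrz <- solve_screened_poisson(tr, f, cl0, screened_config(depth = 5))
  expect_equal(scrz$chi, plain$chi, tolerance = 1e-8)
})

test_that("indicator separates inside from outside on a sphere", {
  cl <- inward_sphere_cloud(800)
  tr <- build_octree(cl, 6)
  f <- splat_vector_field(tr, cl)
  for (solver in c("plain", "screened")) {
    ind <- if (solver == "plain") {
      solve_poisson(tr, f)
    } else {
      solve_screened_poisson(tr, f, compute_sample_weights(cl, 10),
                             screened_config(depth = 6))
    }
    mu <- mean(eval_indicator(ind, cl$points))
    centre <- eval_indicator(ind, rbind(c(0, 0, 0)))
    outside <- eval_indicator(ind, rbind(c(2, 0, 0), c(0, 2, 0)))
    expect_gt(centre - mu, 0)
    expect_lt(max(outside) - mu, 0)
  }
})

test_that("the position constraint pulls the surface toward the samples", {
  cl <- compute_sample_weights(inward_sphere_cloud(800), 10)
  tr <- build_octree(cl, 6)
  f <- splat_vector_field(tr, cl)
  resid <- function(ind) {
    v <- eval_indicator(ind, cl$points)
    mean(abs(v - mean(v)))
  }
  r0 <- resid(solve_poisson(tr, f))
  r1 <- resid(solve_screened_poisson(tr, f, cl, screened_config(depth = 6)))
  expect_lte(r1, r0)
})

test_that("isosurface threshold is the mean sample indicator and the mesh closes", {
  cl <- inward_sphere_cloud(800)  # ~10k points
  tr <- build_octree(cl, 7)
  f <- splat_vector_field(tr, cl)
  ind <- solve_screened_poisson(tr, f, compute_sample_weights(cl, 10),
                                screened_config(depth = 7))
  mesh <- extract_isosurface(ind, cl)
  expect_equal(attr(mesh, "mu_iso"), mean(eval_indicator(ind, cl$points)))
  expect_true(is_watertight(mesh))
  radii <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(abs(mean(radii) - 1), 0.02)
})

test_that("reconstruction is equivariant under translation and scaling", {
  sh <- sample_shape(shape_spec("cube", density = 400))
  m1 <- reconstruct(sh$cloud, depth = 5, smooth = FALSE)
  v1 <- mesh_volume(m1)$volume
  s <- 3.7
  t <- c(12, -5, 40)
  cl2 <- point_cloud(sweep(sh$cloud$points * s, 2, -t))
  m2 <- reconstruct(cl2, depth = 5, smooth = FALSE)
  v2 <- mesh_volume(m2)$volume
  expect_lt(abs(v2 / (v1 * s^3) - 1), 0.005)
})

test_that("reconstruct validates depth before doing any work", {
  sh <- sample_shape(shape_spec("cube", density = 100))
  expect_error(reconstruct(sh$cloud, depth = 3), "\\[4, 12\\]")
  expect_error(screened_config(depth = 13), "\\[4, 12\\]")
  expect_error(screened_config(lambda = -1), ">= 0")
})

test_that("reconstruction of a small cube cloud is watertight and accurate", {
  sh <- sample_shape(shape_spec("cube", density = 900))
  mesh <- reconstruct(sh$cloud, depth = 6)
  expect_true(is_watertight(mesh))
  v <- mesh_volume(mesh)
  expect_lt(abs(v$volume - 1), 0.01)
  rep <- attr(mesh, "report")
  expect_equal(rep$facet_count, nrow(mesh$faces))
  expect_true(all(c("smooth", "solve", "isosurface") %in%
                    names(rep$stage_seconds)))
})
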