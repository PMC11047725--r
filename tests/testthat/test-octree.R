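test_that("octree refines a single point along one path", {
  cl <- point_cloud(rbind(c(0.3, 0.4, 0.5)))
  tr <- build_octree(cl, 2)
  expect_equal(octree_node_counts(tr), c(1L, 1L, 1L))  # levels 0..2
  expect_equal(length(tr$leaf), 1L)
})

test_that("cube corners split into eight depth-1 octants", {
  P <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  tr <- build_octree(point_cloud(P), 1)
  expect_equal(octree_node_counts(tr), c(1L, 8L))
  expect_equal(length(unique(tr$leaf)), 8L)  # one point per child
})

test_that("octree invariants: padding, halving widths, leaf assignment", {
  set.seed(5)
  sh <- sample_shape(shape_spec("cube", density = 300))
  cl <- sh$cloud
  tr <- build_octree(cl, 6)
  expect_equal(tr$width, 1.1, tolerance = 1e-12)  # 10% padding on max extent
  expect_true(all(cl$points >= tr$grid$origin - 1e-12))
  expect_true(all(sweep(cl$points, 2, tr$grid$origin) <= tr$width + 1e-12))
  # every sample lies in exactly one depth-D leaf
  expect_equal(length(tr$leaf), n_points(cl))
  # occupied leaf count equals the brute-force voxel-hash count
  vox <- floor(sweep(cl$points, 2, tr$grid$origin) / (tr$width / 2^6))
  vox <- pmin(pmax(vox, 0), 2^6 - 1)
  nvox <- nrow(unique(vox))
  nleaf <- octree_node_counts(tr)[7]
  expect_equal(nleaf, nvox)
  expect_lte(nleaf, 8L * nvox)
  expect_error(build_octree(cl, 0), "\\[1, 12\\]")
})

test_that("splatting conserves mass and respects symmetry", {
  cl <- point_cloud(rbind(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3)),
                    normals = rbind(c(0, 0, 1), c(0, 1, 0)))
  tr <- build_octree(cl, 4)
  f <- splat_vector_field(tr, cl)
  expect_equal(c(sum(f$Vx), sum(f$Vy), sum(f$Vz)), c(0, 1, 1),
               tolerance = 1e-8)
  # weighted splat scales the mass
  f2 <- splat_vector_field(tr, cl, weights = c(2, 0.5))
  expect_equal(c(sum(f2$Vx), sum(f2$Vy), sum(f2$Vz)), c(0, 0.5, 2),
               tolerance = 1e-8)
  # two antipodal sphere samples with inward normals cancel
  anti <- point_cloud(rbind(c(1, 0, 0), c(-1, 0, 0)),
                      normals = rbind(c(-1, 0, 0), c(1, 0, 0)))
  fa <- splat_vector_field(build_octree(anti, 4), anti)
  expect_lt(abs(sum(fa$Vx)) + abs(sum(fa$Vy)) + abs(sum(fa$Vz)), 1e-8)
})

test_that("the splatted field points along the input normals", {
  sph <- sample_shape(shape_spec("sphere", density = 250))
  cl <- sph$cloud
  cl <- point_cloud(cl$points, normals = -cl$points /
                      sqrt(rowSums(cl$points^2)))  # inward
  tr <- build_octree(cl, 5)
  f <- splat_vector_field(tr, cl)
  g <- tr$grid
  vx <- cloudvol:::eval_grid_cpp(f$Vx, g$origin, g$h, g$g, cl$points)
  vy <- cloudvol:::eval_grid_cpp(f$Vy, g$origin, g$h, g$g, cl$points)
  vz <- cloudvol:::eval_grid_cpp(f$Vz, g$origin, g$h, g$g, cl$points)
  inner <- vx * cl$normals[, 1] + vy * cl$normals[, 2] + vz * cl$normals[, 3]
  expect_gte(mean(inner > 0), 0.99)
})

test_that("dynamic sample weights hit their boundary cases", {
  # centre point with four engineered neighbours
  P <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(-0.1, 0, 0), c(0, 0.1, 0),
             c(0, -0.1, 0), c(5, 5, 5))
  z <- c(0, 0, 1)
  # all neighbour normals identical -> tau = 1
  cl <- point_cloud(P, normals = rbind(z, z, z, z, z, z))
  expect_equal(compute_sample_weights(cl, 4)$confidence[1], 1)
  # all neighbours obtuse -> tau = 0
  cl <- point_cloud(P, normals = rbind(z, -z, -z, -z, -z, z))
  expect_equal(compute_sample_weights(cl, 4)$confidence[1], 0)
  # half aligned, half orthogonal -> tau = 0.5
  x <- c(1, 0, 0)
  cl <- point_cloud(P, normals = rbind(z, z, z, x, x, z))
  expect_equal(compute_sample_weights(cl, 4)$confidence[1], 0.5)
  expect_true(all(compute_sample_weights(cl, 4)$confidence >= 0))
  expect_true(all(compute_sample_weights(cl, 4)$confidence <= 1))
})
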