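# Synthetic fixtures standing in for unavailable livestock scans: closed
# primitive shapes with analytic volumes, a pig-like composite with a
# constructive ground-truth mesh, burr/outlier/occlusion corruption, and
# volume-weight tables following the linear body-weight relation.

#' Describe a synthetic shape
#'
#' @param kind one of `"cube"`, `"cylinder"`, `"sphere"`, `"l_prism"`,
#'   `"thin_plate"`, `"piglet"`.
#' @param side cube / L-prism cross-section side length.
#' @param radius cylinder / sphere radius.
#' @param height cylinder / prism height.
#' @param thickness thin-plate thickness.
#' @param spacing thin-plate sample spacing.
#' @param density surface sampling density, points per unit area.
#' @param jitter in-cell stratified jitter amplitude as a fraction of the
#'   cell size (0 = regular grid sampling, the scanner-like default).
#' @param resolution lattice resolution used to extract the piglet's
#'   constructive mesh.
#' @param seed integer seed making stochastic sampling reproducible.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("cube", "cylinder", "sphere", "l_prism",
                                "thin_plate", "piglet"),
                       side = 1, radius = 1, height = 1, thickness = 0.05,
                       spacing = 0.02, density = 1e4, jitter = 0,
                       resolution = 128L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(side > 0, radius > 0, height > 0, thickness > 0, spacing > 0,
            density > 0, jitter >= 0, jitter < 1)
  structure(list(kind = kind, side = side, radius = radius, height = height,
                 thickness = thickness, spacing = spacing, density = density,
                 jitter = jitter, resolution = as.integer(resolution),
                 seed = as.integer(seed)),
            class = "shape_spec")
}

# stratified cell-centred sampling of the parallelogram corner + s*e1 + t*e2
sample_face_grid <- function(corner, e1, e2, n1, n2, jitter = 0) {
  i <- rep(seq_len(n1) - 0.5, times = n2)
  j <- rep(seq_len(n2) - 0.5, each = n1)
  if (jitter > 0) {
    i <- i + runif(length(i), -jitter / 2, jitter / 2)
    j <- j + runif(length(j), -jitter / 2, jitter / 2)
  }
  cbind(corner[1] + i / n1 * e1[1] + j / n2 * e2[1],
        corner[2] + i / n1 * e1[2] + j / n2 * e2[2],
        corner[3] + i / n1 * e1[3] + j / n2 * e2[3])
}

sample_cube <- function(side, density, jitter) {
  n <- max(2L, round(side * sqrt(density)))
  s <- side
  faces <- list(
    list(c(0, 0, 0), c(s, 0, 0), c(0, s, 0)),  # bottom z=0
    list(c(0, 0, s), c(s, 0, 0), c(0, s, 0)),  # top z=s
    list(c(0, 0, 0), c(s, 0, 0), c(0, 0, s)),  # y=0
    list(c(0, s, 0), c(s, 0, 0), c(0, 0, s)),  # y=s
    list(c(0, 0, 0), c(0, s, 0), c(0, 0, s)),  # x=0
    list(c(s, 0, 0), c(0, s, 0), c(0, 0, s))   # x=s
  )
  do.call(rbind, lapply(faces, function(f)
    sample_face_grid(f[[1]], f[[2]], f[[3]], n, n, jitter)))
}

sample_cylinder <- function(radius, height, density, jitter) {
  # lateral wall
  ntheta <- max(8L, round(2 * pi * radius * sqrt(density)))
  nz <- max(2L, round(height * sqrt(density)))
  th <- (rep(seq_len(ntheta) - 0.5, times = nz)) / ntheta * 2 * pi
  zz <- (rep(seq_len(nz) - 0.5, each = ntheta)) / nz * height
  if (jitter > 0) {
    th <- th + runif(length(th), -jitter, jitter) * 2 * pi / ntheta
    zz <- zz + runif(length(zz), -jitter, jitter) * height / nz
  }
  lateral <- cbind(radius * cos(th), radius * sin(th), zz)
  # caps: concentric rings of matched linear density
  nr <- max(1L, round(radius * sqrt(density)))
  dr <- radius / nr
  cap <- do.call(rbind, lapply(seq_len(nr), function(j) {
    rj <- (j - 0.5) * dr
    m <- max(4L, round(2 * pi * rj / dr))
    a <- (seq_len(m) - 0.5) / m * 2 * pi
    cbind(rj * cos(a), rj * sin(a), 0)
  }))
  cap <- rbind(cap, c(0, 0, 0))
  top <- cap
  top[, 3] <- height
  rbind(lateral, cap, top)
}

sample_sphere <- function(radius, density) {
  n <- max(16L, round(4 * pi * radius^2 * density))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(radius * sin(phi) * cos(theta),
        radius * sin(phi) * sin(theta),
        radius * cos(phi))
}

l_prism_polygon <- function(side) {
  s <- side
  rbind(c(0, 0), c(s, 0), c(s, s / 2), c(s / 2, s / 2), c(s / 2, s), c(0, s))
}

point_in_l <- function(xy, side) {
  s <- side
  inside_sq <- xy[, 1] >= 0 & xy[, 1] <= s & xy[, 2] >= 0 & xy[, 2] <= s
  cut_out <- xy[, 1] > s / 2 & xy[, 2] > s / 2
  inside_sq & !cut_out
}

sample_l_prism <- function(side, height, density, jitter) {
  poly <- l_prism_polygon(side)
  np <- nrow(poly)
  walls <- do.call(rbind, lapply(seq_len(np), function(i) {
    a <- poly[i, ]
    b <- poly[if (i == np) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n1 <- max(2L, round(len * sqrt(density)))
    n2 <- max(2L, round(height * sqrt(density)))
    sample_face_grid(c(a, 0), c(b - a, 0), c(0, 0, height), n1, n2, jitter)
  }))
  # caps: stratified grid over the bounding square, rejected outside the L
  n <- max(2L, round(side * sqrt(density)))
  g <- sample_face_grid(c(0, 0, 0), c(side, 0, 0), c(0, side, 0), n, n, jitter)
  g <- g[point_in_l(g[, 1:2, drop = FALSE], side), , drop = FALSE]
  top <- g
  top[, 3] <- height
  rbind(walls, g, top)
}

sample_thin_plate <- function(side, thickness, spacing, jitter) {
  nxy <- max(2L, round(side / spacing))
  nz <- max(1L, round(thickness / spacing))
  s <- side
  t <- thickness
  faces <- list(
    list(c(0, 0, 0), c(s, 0, 0), c(0, s, 0), nxy, nxy),  # bottom
    list(c(0, 0, t), c(s, 0, 0), c(0, s, 0), nxy, nxy),  # top
    list(c(0, 0, 0), c(s, 0, 0), c(0, 0, t), nxy, nz),   # y=0 rim
    list(c(0, s, 0), c(s, 0, 0), c(0, 0, t), nxy, nz),   # y=s rim
    list(c(0, 0, 0), c(0, s, 0), c(0, 0, t), nxy, nz),   # x=0 rim
    list(c(s, 0, 0), c(0, s, 0), c(0, 0, t), nxy, nz)    # x=s rim
  )
  do.call(rbind, lapply(faces, function(f)
    sample_face_grid(f[[1]], f[[2]], f[[3]], f[[4]], f[[5]], jitter)))
}

# ---- piglet composite ------------------------------------------------------

piglet_parts <- function() {
  list(
    torso = list(type = "ellipsoid", center = c(0, 0, 0.42),
                 axes = c(0.34, 0.13, 0.15)),
    head = list(type = "ellipsoid", center = c(0.40, 0, 0.46),
                axes = c(0.13, 0.095, 0.10)),
    leg1 = list(type = "capsule", a = c(0.20, 0.085, 0.10),
                b = c(0.20, 0.085, 0.42), r = 0.04),
    leg2 = list(type = "capsule", a = c(0.20, -0.085, 0.10),
                b = c(0.20, -0.085, 0.42), r = 0.04),
    leg3 = list(type = "capsule", a = c(-0.20, 0.085, 0.10),
                b = c(-0.20, 0.085, 0.42), r = 0.04),
    leg4 = list(type = "capsule", a = c(-0.20, -0.085, 0.10),
                b = c(-0.20, -0.085, 0.42), r = 0.04)
  )
}

# signed distance (negative inside) of the implicit union
piglet_sdf <- function(P) {
  parts <- piglet_parts()
  d <- rep(Inf, nrow(P))
  for (p in parts) {
    if (p$type == "ellipsoid") {
      Q <- sweep(sweep(P, 2L, p$center), 2L, p$axes, "/")
      dp <- (sqrt(rowSums(Q^2)) - 1) * min(p$axes)
    } else {
      ab <- p$b - p$a
      tt <- pmin(pmax((sweep(P, 2L, p$a) %*% ab) / sum(ab^2), 0), 1)
      proj <- sweep(tt %*% matrix(ab, 1L), 2L, -p$a)
      dp <- sqrt(rowSums((P - proj)^2)) - p$r
    }
    d <- pmin(d, dp)
  }
  d
}

#' Constructive piglet mesh
#'
#' Extracts the piglet composite (ellipsoid torso and head, four capsule
#' legs) from its implicit union by marching tetrahedra at the requested
#' lattice resolution. The tetrahedral-summation volume of this mesh is the
#' ground truth carried by the piglet fixture (the composite is synthetic --
#' it plays the role of a real scanned piglet model, it does not reproduce
#' one).
#'
#' @param resolution lattice nodes per axis (default 128).
#' @return a watertight [triangle_mesh()].
#' @export
piglet_mesh <- function(resolution = 128L) {
  g <- as.integer(resolution)
  lo <- c(-0.60, -0.22, 0.02)
  hi <- c(0.60, 0.22, 0.62)
  width <- max(hi - lo)
  h <- width / (g - 1)
  ax <- lo[1] + (seq_len(g) - 1) * h
  ay <- lo[2] + (seq_len(g) - 1) * h
  az <- lo[3] + (seq_len(g) - 1) * h
  P <- cbind(rep(ax, times = g * g),
             rep(rep(ay, each = g), times = g),
             rep(az, each = g * g))
  f <- piglet_sdf(P)  # negative inside; marching expects positive inside
  res <- march_tets_cpp(-f, g, lo, h)
  mesh <- triangle_mesh(res$vertices, res$faces)
  if (mesh_signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

# area-weighted per-face sampling of a mesh surface (stratified per patch)
sample_mesh_surface <- function(mesh, density) {
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind((B[, 2] - A[, 2]) * (C[, 3] - A[, 3]) -
                (B[, 3] - A[, 3]) * (C[, 2] - A[, 2]),
              (B[, 3] - A[, 3]) * (C[, 1] - A[, 1]) -
                (B[, 1] - A[, 1]) * (C[, 3] - A[, 3]),
              (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) -
                (B[, 2] - A[, 2]) * (C[, 1] - A[, 1]))
  area <- sqrt(rowSums(cr^2)) / 2
  expect <- area * density
  cnt <- floor(expect) + (runif(length(expect)) < (expect - floor(expect)))
  tot <- sum(cnt)
  fi <- rep.int(seq_along(cnt), cnt)
  u <- runif(tot)
  v <- runif(tot)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  A[fi, , drop = FALSE] * (1 - u - v) + B[fi, , drop = FALSE] * u +
    C[fi, , drop = FALSE] * v
}

#' Sample a synthetic shape's surface
#'
#' Deterministic (seeded) stratified surface sampling of the described
#' shape, returned together with its ground-truth volume: analytic for the
#' primitives (cube `s^3`, cylinder `pi r^2 h`, sphere `4 pi r^3 / 3`,
#' L-prism by decomposition, thin plate `s^2 t`), and the
#' tetrahedral-summation volume of the constructive mesh for the piglet.
#'
#' @param spec a [shape_spec()].
#' @return list with `cloud` (a [point_cloud()]), `volume` (ground truth)
#'   and `spec`.
#' @export
sample_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  set.seed(spec$seed)
  pts <- switch(spec$kind,
    cube = sample_cube(spec$side, spec$density, spec$jitter),
    cylinder = sample_cylinder(spec$radius, spec$height, spec$density,
                               spec$jitter),
    sphere = sample_sphere(spec$radius, spec$density),
    l_prism = sample_l_prism(spec$side, spec$height, spec$density,
                             spec$jitter),
    thin_plate = sample_thin_plate(spec$side, spec$thickness, spec$spacing,
                                   spec$jitter),
    piglet = NULL)
  vol <- switch(spec$kind,
    cube = spec$side^3,
    cylinder = pi * spec$radius^2 * spec$height,
    sphere = 4 / 3 * pi * spec$radius^3,
    l_prism = 0.75 * spec$side^2 * spec$height,
    thin_plate = spec$side^2 * spec$thickness,
    piglet = NA_real_)
  if (spec$kind == "piglet") {
    mesh <- piglet_mesh(spec$resolution)
    pts <- sample_mesh_surface(mesh, spec$density)
    vol <- mesh_volume(mesh)$volume
  }
  list(cloud = point_cloud(pts), volume = vol, spec = spec)
}

#' Describe point-cloud corruption
#'
#' Emulates scanner artifacts: Gaussian jitter along the local normal (burr
#' noise), a fraction of points pushed out as outlier burrs, and an optional
#' occlusion predicate deleting points (e.g. a leg hidden by a railing).
#'
#' @param sigma standard deviation of the Gaussian along-normal jitter
#'   (length units; 0 disables).
#' @param outlier_fraction fraction of points replaced by outliers, in
#'   `[0, 1)`.
#' @param outlier_scale offset length of the outlier burrs.
#' @param occlusion `NULL`, or a predicate `function(points)` returning a
#'   logical vector (TRUE = remove). See [occlusion_box()].
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, outlier_fraction = 0, outlier_scale = 0,
                       occlusion = NULL) {
  stopifnot(sigma >= 0, outlier_fraction >= 0, outlier_fraction < 1,
            outlier_scale >= 0,
            is.null(occlusion) || is.function(occlusion))
  structure(list(sigma = sigma, outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale, occlusion = occlusion),
            class = "noise_spec")
}

#' Axis-aligned box occlusion predicate
#'
#' @param lo,hi numeric length-3 box corners.
#' @return a predicate usable as `occlusion` in [noise_spec()].
#' @export
occlusion_box <- function(lo, hi) {
  force(lo); force(hi)
  function(points) {
    points[, 1] >= lo[1] & points[, 1] <= hi[1] &
      points[, 2] >= lo[2] & points[, 2] <= hi[2] &
      points[, 3] >= lo[3] & points[, 3] <= hi[3]
  }
}

#' Corrupt a point cloud
#'
#' Applies, in order: seeded Gaussian displacement along the local normal
#' (or a random unit direction if the cloud has no normals), replacement of
#' `round(outlier_fraction * n)` points by outliers offset by
#' `outlier_scale`, and deletion of points inside the occlusion region.
#' Reproducible per seed.
#'
#' @param cloud a [point_cloud()].
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return the corrupted [point_cloud()].
#' @export
corrupt <- function(cloud, noise, seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(noise, "noise_spec"))
  set.seed(as.integer(seed))
  P <- cloud$points
  n <- nrow(P)
  dirs <- cloud$normals
  if (is.null(dirs)) {
    d <- matrix(rnorm(3 * n), n, 3)
    dirs <- d / sqrt(rowSums(d^2))
  }
  if (noise$sigma > 0) {
    P <- P + dirs * rnorm(n, 0, noise$sigma)
  }
  n_out <- round(noise$outlier_fraction * n)
  if (n_out > 0) {
    pick <- sample.int(n, n_out)
    P[pick, ] <- P[pick, , drop = FALSE] +
      dirs[pick, , drop = FALSE] * noise$outlier_scale
  }
  keep <- rep(TRUE, n)
  if (!is.null(noise$occlusion)) keep <- !noise$occlusion(P)
  point_cloud(P[keep, , drop = FALSE],
              normals = if (!is.null(cloud$normals))
                cloud$normals[keep, , drop = FALSE],
              confidence = if (!is.null(cloud$confidence))
                cloud$confidence[keep])
}

#' Generate a synthetic volume-weight table
#'
#' Volumes uniform over `volume_range`; weights `a * v + b + N(0, sigma_kg)`.
#' Defaults emulate the published herd: slope/intercept of the body-weight
#' line, volume range back-computed from the 83-132 kg weight range, and
#' `sigma_kg` calibrated in closed form so the population R^2 is about 0.92
#' (see the methods vignette).
#'
#' @param n number of animals.
#' @param a slope (kg per volume unit).
#' @param b intercept (kg).
#' @param sigma_kg Gaussian weight-noise standard deviation.
#' @param volume_range range the volumes are drawn from, (input unit)^3.
#' @param seed integer seed.
#' @return data.frame with columns `volume`, `weight`.
#' @export
make_volume_weight_table <- function(n = 300L, a = 1070.4, b = -1.6524,
                                     sigma_kg = 4.1,
                                     volume_range = c(0.0791, 0.1249),
                                     seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  set.seed(as.integer(seed))
  v <- runif(n, volume_range[1], volume_range[2])
  w <- a * v + b + rnorm(n, 0, sigma_kg)
  data.frame(volume = v, weight = w)
}
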