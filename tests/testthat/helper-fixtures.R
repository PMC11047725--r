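# Fixtures built in code: canonical meshes with known volumes and small
# reference oracles, shared across the test files.

# unit cube [0,1]^3, 12 consistently outward-wound triangles
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(1, 5, 8), c(1, 8, 4),   # left (-x)
             c(2, 3, 7), c(2, 7, 6))   # right (+x)
  triangle_mesh(v, f)
}

# icosphere: subdivided icosahedron projected onto the radius-r sphere
icosphere_mesh <- function(subdiv = 4L, r = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- midcache[[key]]
      if (!is.null(got)) return(got)
      m <- (v[a, ] + v[b, ]) / 2
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      midcache[[key]] <- id
      id
    }
    nf <- nrow(f)
    fout <- matrix(0L, nf * 4L, 3L)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      fout[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- fout
  }
  v <- v * (r / sqrt(rowSums(v^2)))
  triangle_mesh(v, f)
}

# closed cylinder (radius r, height h), nseg angular segments, nz side rings;
# the enclosed solid is exactly the prism over the inscribed n-gon
cylinder_mesh <- function(r = 1, h = 1, nseg = 64L, nz = 1L) {
  th <- (seq_len(nseg) - 1) / nseg * 2 * pi
  rings <- lapply(0:nz, function(k) cbind(r * cos(th), r * sin(th), h * k / nz))
  v <- do.call(rbind, rings)
  nvr <- nseg
  side <- list()
  for (k in seq_len(nz)) {
    b0 <- (k - 1L) * nvr
    t0 <- k * nvr
    for (i in seq_len(nseg)) {
      j <- if (i == nseg) 1L else i + 1L
      side[[length(side) + 1L]] <- rbind(c(b0 + i, b0 + j, t0 + j),
                                         c(b0 + i, t0 + j, t0 + i))
    }
  }
  cb <- nrow(v) + 1L  # bottom centre
  ct <- nrow(v) + 2L  # top centre
  v <- rbind(v, c(0, 0, 0), c(0, 0, h))
  caps <- list()
  for (i in seq_len(nseg)) {
    j <- if (i == nseg) 1L else i + 1L
    caps[[length(caps) + 1L]] <- rbind(c(cb, j, i),                 # bottom, -z
                                       c(ct, nz * nvr + i, nz * nvr + j))  # top, +z
  }
  triangle_mesh(v, do.call(rbind, c(side, caps)))
}

# O(n^2) brute-force k-nearest-neighbour oracle with the same tie-break
brute_knn <- function(P, k) {
  n <- nrow(P)
  D <- as.matrix(dist(P))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- d[ord]
  }
  list(idx = idx, dist = dst)
}

# the printed determinant expansion for the origin tetrahedron (oracle form)
tet_volume_expansion <- function(a, b, c) {
  x1 <- a[1]; y1 <- a[2]; z1 <- a[3]
  x2 <- b[1]; y2 <- b[2]; z2 <- b[3]
  x3 <- c[1]; y3 <- c[2]; z3 <- c[3]
  (-x3 * y2 * z1 + x2 * y3 * z1 + x3 * y1 * z2 - x1 * y3 * z2 -
     x2 * y1 * z3 + x1 * y2 * z3) / 6
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
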