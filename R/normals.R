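#' Estimate unoriented normals by local PCA
#'
#' For each point the covariance `C = X'X / k` of its k-neighbourhood
#' (rows of `X` are neighbour offsets from the point itself) is
#' eigen-decomposed; the unit eigenvector with the smallest eigenvalue is the
#' estimated normal line. The sign is arbitrary at this stage -- use
#' [orient_normals_mst()] to obtain a globally consistent orientation.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbourhood size, `k >= 3`.
#' @return the cloud with `normals` set (unit vectors, arbitrary sign).
#' @export
estimate_normals_pca <- function(cloud, k = 20L) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3 for a PCA normal")
  nb <- knn(cloud, k)
  normals <- pca_normals_cpp(cloud$points, nb$idx)
  point_cloud(cloud$points, normals = normals, confidence = cloud$confidence)
}

#' Orient normals by maximum-spanning-tree propagation
#'
#' Builds the symmetrized KNN graph over the cloud and assigns each edge the
#' weight `E(i,j) = psi(i,j) * omega(|x_i - x_j|)`, where `omega` is a
#' Gaussian distance decay and `psi` measures how much the two endpoint
#' normal lines agree:
#' \itemize{
#'   \item `mode = "distance"`: `psi = |<n_i, n_j>|`;
#'   \item `mode = "tangency"`: `psi = |<n_i', n_j>|` with `n_i'` the
#'     component of `n_i` orthogonal to the edge direction. An edge lying in
#'     the tangent plane leaves `n_i' = n_i` (tangency reduces to distance
#'     mode); an edge parallel to the normal -- e.g. jumping across a thin
#'     plate -- gets weight near zero, so the spanning tree avoids it.
#' }
#' The maximum spanning tree of this graph is extracted, the sign of the seed
#' normal (the point with maximal z) is fixed to point against +z (the inward
#' convention: at the top of a shape the interior lies below), and signs are
#' propagated along tree edges, flipping a child normal whenever its inner
#' product with the (tangency-corrected) parent normal is negative.
#'
#' @param cloud a [point_cloud()] with normals present.
#' @param k neighbourhood size of the orientation graph.
#' @param mode `"tangency"` (default) or `"distance"` edge weights.
#' @return the cloud with consistently signed (inward) normals; attribute
#'   `n_flipped` counts sign changes relative to the input.
#' @export
orient_normals_mst <- function(cloud, k = 10L, mode = c("tangency", "distance")) {
  stopifnot(inherits(cloud, "point_cloud"))
  mode <- match.arg(mode)
  if (is.null(cloud$normals)) stop("cloud has no normals; run estimate_normals_pca first")
  P <- cloud$points
  N <- cloud$normals
  n <- nrow(P)
  nb <- knn(cloud, as.integer(k))

  ii <- rep.int(seq_len(n), nb$k)
  jj <- as.vector(nb$idx)
  dd <- as.vector(nb$dist)
  # symmetrize and deduplicate undirected edges
  a <- pmin(ii, jj)
  b <- pmax(ii, jj)
  keep <- !duplicated(a * (n + 1) + b)
  a <- a[keep]; b <- b[keep]; dd <- dd[keep]

  h <- mean(nb$dist)
  omega <- exp(-(dd * dd) / (h * h))
  if (mode == "distance") {
    psi <- abs(rowSums(N[a, , drop = FALSE] * N[b, , drop = FALSE]))
  } else {
    e <- P[a, , drop = FALSE] - P[b, , drop = FALSE]
    e <- e / pmax(sqrt(rowSums(e^2)), 1e-300)
    na <- N[a, , drop = FALSE]
    proj <- rowSums(e * na)
    na_t <- na - e * proj
    psi <- abs(rowSums(na_t * N[b, , drop = FALSE]))
  }
  w <- psi * omega

  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    warning(sprintf("orientation graph has %d components (sizes: %s); %s",
                    comps$no, paste(comps$csize, collapse = ", "),
                    "orienting each component separately"))
  }
  # maximum spanning tree as minimum spanning tree on negated weights
  tree <- igraph::mst(g, weights = -w)
  te <- igraph::as_edgelist(tree, names = FALSE)

  adj_i <- c(te[, 1], te[, 2])
  adj_j <- c(te[, 2], te[, 1])
  ord <- order(adj_i)
  adj_i <- adj_i[ord]; adj_j <- adj_j[ord]
  ptr <- c(0L, cumsum(tabulate(adj_i, n)))

  sign_vec <- rep(1, n)
  visited <- rep(FALSE, n)
  n_flipped <- 0L
  for (comp in seq_len(comps$no)) {
    members <- which(comps$membership == comp)
    seed <- members[which.max(P[members, 3])]
    # seed convention: normal points against +z (inward at the top)
    if (sum(N[seed, ] * c(0, 0, 1)) > 0) sign_vec[seed] <- -1
    visited[seed] <- TRUE
    queue <- integer(length(members))
    queue[1] <- seed
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      np <- sign_vec[p] * N[p, ]
      if (ptr[p] < ptr[p + 1L]) {
        for (ei in seq.int(ptr[p] + 1L, ptr[p + 1L])) {
          child <- adj_j[ei]
          if (visited[child]) next
          visited[child] <- TRUE
          npp <- np
          if (mode == "tangency") {
            ev <- P[p, ] - P[child, ]
            evn <- sqrt(sum(ev^2))
            if (evn > 1e-300) {
              ev <- ev / evn
              npp <- np - ev * sum(ev * np)
            }
          }
          if (sum(npp * N[child, ]) < 0) sign_vec[child] <- -1
          tail <- tail + 1L
          queue[tail] <- child
        }
      }
    }
  }
  n_flipped <- sum(sign_vec < 0)
  out <- point_cloud(P, normals = N * sign_vec, confidence = cloud$confidence)
  attr(out, "n_flipped") <- n_flipped
  out
}
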