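#' Build an adaptive octree over a point cloud
#'
#' The root cell is the axis-aligned bounding cube of the cloud expanded by
#' 10%; cells are refined (child width = parent width / 2) only along the
#' point set, down to `depth` levels, and every sample is assigned to its
#' unique depth-`D` leaf. The complete depth-`D` level also defines the
#' uniform function-space lattice (`2^D` nodes per axis over the root cube)
#' on which the indicator solve is discretized.
#'
#' @param cloud a [point_cloud()].
#' @param depth octree depth `D`, an integer in `[4, 12]` (the effective
#'   lattice resolution is `2^D` per axis).
#' @return an object of class `octree` with fields `depth`, `center`,
#'   `width`, `nodes` (list of occupied-cell index matrices, one per level
#'   0..D), `leaf` (per-point leaf id at depth D) and `grid` (lattice origin,
#'   spacing `h` and size `g`).
#' @export
build_octree <- function(cloud, depth) {
  stopifnot(inherits(cloud, "point_cloud"))
  depth <- as.integer(depth)
  # reconstruction restricts depth to [4, 12] (see screened_config); the bare
  # octree accepts shallower trees so the partition contracts stay testable
  if (is.na(depth) || depth < 1L || depth > 12L) {
    stop("depth must be an integer in [1, 12]")
  }
  P <- cloud$points
  lo <- apply(P, 2L, min)
  hi <- apply(P, 2L, max)
  center <- (lo + hi) / 2
  width <- max(hi - lo) * 1.1
  if (width <= 0) width <- 1.0  # degenerate single-point cloud
  origin <- center - width / 2

  nleaf <- 2L^depth
  vox <- floor(sweep(sweep(P, 2L, origin), 2L, width / nleaf, "/"))
  storage.mode(vox) <- "integer"
  vox[vox < 0L] <- 0L
  vox[vox > nleaf - 1L] <- nleaf - 1L

  nodes <- vector("list", depth + 1L)
  v <- vox
  leaf_key <- v[, 1] + as.numeric(nleaf) * (v[, 2] + as.numeric(nleaf) * v[, 3])
  for (d in seq.int(depth, 0L)) {
    key <- v[, 1] + as.numeric(2L^d) * (v[, 2] + as.numeric(2L^d) * v[, 3])
    nodes[[d + 1L]] <- v[!duplicated(key), , drop = FALSE]
    v <- v %/% 2L
  }

  g <- 2L^depth
  h <- width / (g - 1)
  structure(list(depth = depth, center = center, width = width,
                 nodes = nodes, leaf = leaf_key,
                 grid = list(g = g, h = h, origin = origin)),
            class = "octree")
}

#' @export
print.octree <- function(x, ...) {
  cat(sprintf("<octree> depth %d, root width %.4g, %d occupied leaves\n",
              x$depth, x$width, nrow(x$nodes[[x$depth + 1L]])))
  invisible(x)
}

#' Number of occupied octree nodes per level
#' @param tree an [build_octree()] result.
#' @return integer vector of length `depth + 1` (levels 0..D).
#' @export
octree_node_counts <- function(tree) {
  vapply(tree$nodes, nrow, 0L)
}
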