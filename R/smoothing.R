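#' Moving-least-squares smoothing configuration
#'
#' @param k neighbourhood size used for each local fit. Must leave a margin
#'   over the number of polynomial basis terms (10 for the full quadratic
#'   basis in 3-space, of which the rotation-closed bivariate height-field
#'   subset is fitted).
#' @param basis `"quadratic"` (default) or `"linear"` local polynomial.
#' @param bandwidth positive multiplier for the Gaussian distance-weight
#'   scale: the kernel scale is `bandwidth` times the mean neighbour distance.
#' @return an object of class `mls_config`.
#' @export
mls_config <- function(k = 30L, basis = c("quadratic", "linear"),
                       bandwidth = 2.0) {
  basis <- match.arg(basis)
  k <- as.integer(k)
  m <- if (basis == "quadratic") 10L else 4L
  if (k < m) {
    stop(sprintf("k = %d too small for the %s basis (needs >= %d)", k, basis, m))
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  structure(list(k = k, basis = basis, bandwidth = bandwidth),
            class = "mls_config")
}

#' Smooth a point cloud by moving-least-squares projection
#'
#' Each point is projected onto a weighted-least-squares polynomial surface
#' fitted over its k-neighbourhood: a weighted PCA plane defines a local
#' frame, a bivariate polynomial height field is fitted with Gaussian
#' distance weights `w(d) = exp(-d^2/h^2)` (`h` = bandwidth x mean neighbour
#' distance), and the point moves to the fitted surface along the plane
#' normal. Polynomials up to the basis order are reproduced exactly, so
#' already-smooth clouds are (near-)fixed points.
#'
#' Rank-deficient local fits fall back to a best-fit-plane projection for the
#' affected point, with a warning reporting how many points were affected.
#'
#' @param cloud a [point_cloud()] with at least `k + 1` points.
#' @param config an [mls_config()].
#' @return a smoothed [point_cloud()] of equal cardinality (normals and
#'   confidence are dropped: they must be re-estimated on the new positions).
#' @export
mls_smooth <- function(cloud, config = mls_config()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(config, "mls_config"))
  if (n_points(cloud) < config$k + 1L) {
    stop("cloud must have at least k + 1 points")
  }
  nb <- knn(cloud, config$k)
  order <- if (config$basis == "quadratic") 2L else 1L
  res <- mls_smooth_cpp(cloud$points, nb$idx, nb$dist, order, config$bandwidth)
  if (res$n_fallback > 0L) {
    warning(sprintf("MLS fit rank-deficient at %d point(s); %s",
                    res$n_fallback, "used best-fit-plane projection there"))
  }
  point_cloud(res$points)
}
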