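#' k-nearest-neighbor search
#'
#' Exact Euclidean k-nearest neighbors for every point of a cloud, self
#' included. Ties in distance are broken by point index, so the result is
#' fully deterministic. The search is blocked brute force: exact, no spatial
#' index, adequate for the cloud sizes this toolkit produces (10^3-10^4
#' points).
#'
#' @param points numeric matrix, N x 3 (or a `labeled_cloud`)
#' @param k neighborhood size, `3 <= k <= N` (k = 1 and 2 are allowed and
#'   return self / self + nearest)
#' @param block number of query rows per distance block (memory knob)
#' @return integer matrix N x k; row i holds the indices of the k nearest
#'   neighbors of point i in order of increasing distance (row i always
#'   starts with i itself)
#' @export
knn <- function(points, k, block = 512L) {
  if (inherits(points, "labeled_cloud")) points <- points$points
  points <- as_points(points)
  n <- nrow(points)
  if (k < 1) stop("'k' must be >= 1")
  if (k > n) stop(sprintf("'k' (%d) exceeds the number of points (%d)", k, n))
  out <- matrix(0L, n, k)
  sq <- rowSums(points^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # squared distances, clamped at 0 against rounding
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(points[idx, , drop = FALSE], points)
    d2[d2 < 0] <- 0
    for (r in seq_along(idx)) {
      o <- order(d2[r, ], seq_len(n))[seq_len(k)]
      out[idx[r], ] <- o
    }
  }
  out
}

#' Surface normals and curvature by local PCA
#'
#' For each point, the covariance of its k-neighborhood is eigendecomposed;
#' the normal is the eigenvector of the smallest eigenvalue and the
#' curvature is the "surface variation" lambda_min / (lambda_1 + lambda_2 +
#' lambda_3), which lies in [0, 1/3]. Normals are oriented toward
#' `view_origin` (the sensor position), giving a consistent approach
#' direction for probe planning. A neighborhood whose covariance is
#' numerically zero (all points coincident) yields curvature 0 and is
#' flagged invalid.
#'
#' @param points N x 3 matrix or `labeled_cloud`
#' @param k neighborhood size, >= 3
#' @param view_origin length-3 sensor position used to orient normals
#' @param neighbors optional precomputed `knn(points, k)` table
#' @return object of class `normal_field`: list with `normals` (N x 3 unit
#'   rows), `curvatures` (N, in [0, 1/3]), `valid` (logical N), `k`
#' @export
estimate_normals_curvature <- function(points, k = 10L, view_origin = c(0, 0, 2),
                                       neighbors = NULL) {
  if (inherits(points, "labeled_cloud")) points <- points$points
  points <- as_points(points)
  n <- nrow(points)
  if (k < 3) stop("'k' must be >= 3 for a plane fit")
  if (is.null(neighbors)) neighbors <- knn(points, k)
  normals <- matrix(NA_real_, n, 3)
  curv <- numeric(n)
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    nb <- points[neighbors[i, ], , drop = FALSE]
    ctr <- sweep(nb, 2, colMeans(nb))
    cv <- crossprod(ctr) / nrow(ctr)
    tr <- sum(diag(cv))
    if (tr < 1e-18) {
      curv[i] <- 0
      valid[i] <- FALSE
      next
    }
    e <- eigen(cv, symmetric = TRUE)
    nrm <- e$vectors[, 3]
    d <- sum(nrm * (view_origin - points[i, ]))
    if (d < 0 || (d == 0 && any(nrm != canonical_sign(nrm)))) nrm <- -nrm
    normals[i, ] <- nrm / vnorm(nrm)
    curv[i] <- max(0, e$values[3]) / tr
  }
  structure(list(normals = normals, curvatures = curv, valid = valid, k = k),
            class = "normal_field")
}

#' @export
print.normal_field <- function(x, ...) {
  cat(sprintf("<normal_field> %d points, k = %d, %d invalid\n",
              nrow(x$normals), x$k, sum(!x$valid)))
  cat(sprintf("  curvature range: [%.4g, %.4g]\n",
              min(x$curvatures), max(x$curvatures)))
  invisible(x)
}

#' Principal axes of a point set
#'
#' Covariance eigenvectors ordered by decreasing eigenvalue (major, minor,
#' normal), with each axis sign-fixed so its first nonzero component is
#' positive. Extents are the ranges of the point projections along each
#' axis; leaf slicing runs along the major axis.
#'
#' @param points M x 3 matrix, M >= 3
#' @return list with `centroid`, `axes` (3 x 3, columns = major, minor,
#'   normal), `extents` (length 3, same units as the input), `eigenvalues`
#' @export
principal_axes <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 3) stop("need at least 3 points for principal axes")
  ctr <- colMeans(points)
  dev <- sweep(points, 2, ctr)
  e <- eigen(crossprod(dev) / nrow(points), symmetric = TRUE)
  axes <- apply(e$vectors, 2, canonical_sign)
  proj <- dev %*% axes
  extents <- apply(proj, 2, function(p) diff(range(p)))
  list(centroid = ctr, axes = axes, extents = extents, eigenvalues = e$values)
}
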