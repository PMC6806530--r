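#' Segmentation parameters
#'
#' Controls for region growing with a smoothness constraint. `theta_smooth`
#' is the maximum angle (degrees) between the normal of a point already in
#' the region and a neighbor joining it; `c_max` is the curvature bound a
#' joined point must satisfy to itself seed further growth; regions smaller
#' than `min_size` are rejected as noise. Raising `theta_smooth` merges
#' regions (coarser leaf segments), lowering it splits curved leaves into
#' several smooth patches, which is how a twisted maize-like leaf yields
#' multiple probing regions while a flat soybean-like leaflet stays whole.
#'
#' @param theta_smooth degrees, in (0, 90)
#' @param c_max curvature (surface-variation) threshold in [0, 1/3]
#' @param min_size minimum points per segment, >= 3
#' @param k neighborhood size used for growing (and for the normal field)
#' @return object of class `segmentation_params`
#' @export
segmentation_params <- function(theta_smooth = 10, c_max = 0.05,
                                min_size = 100L, k = 10L) {
  if (theta_smooth <= 0 || theta_smooth >= 90)
    stop("'theta_smooth' must lie strictly between 0 and 90 degrees")
  if (c_max < 0 || c_max > 1 / 3) stop("'c_max' must lie in [0, 1/3]")
  if (min_size < 3) stop("'min_size' must be >= 3")
  structure(list(theta_smooth = theta_smooth, c_max = c_max,
                 min_size = as.integer(min_size), k = as.integer(k)),
            class = "segmentation_params")
}

#' Region growing with smoothness constraint
#'
#' Extracts piecewise-smooth point clusters (leaf segments) and rejects the
#' rest as noise. Seeds are processed in order of increasing curvature (ties
#' by point index). From a growth point p, each unassigned k-neighbor q
#' joins p's region if the angle between q's normal and the normal of the
#' region's seed is at most `theta_smooth`; q additionally becomes a growth
#' point only if its curvature is at most `c_max`. Comparing against the
#' seed normal bounds the total normal variation inside one segment, so a
#' smoothly twisting surface is cut into patches of bounded orientation
#' span — a comparison against each local normal would chain through any
#' gradual twist and never split it. Completed regions below `min_size`
#' points, and points with invalid normals, are moved to the noise set. The
#' procedure is deterministic for a fixed input.
#'
#' @param cloud `labeled_cloud` or N x 3 matrix
#' @param field `normal_field` computed on the same points with `params$k`
#' @param params `segmentation_params`
#' @return object of class `leaf_segmentation`: `segments` (list of integer
#'   index vectors, largest first), `noise` (integer vector), `params`.
#'   Segments and noise partition the cloud.
#' @export
region_grow <- function(cloud, field, params = segmentation_params()) {
  pts <- if (inherits(cloud, "labeled_cloud")) cloud$points else as_points(cloud)
  if (!inherits(field, "normal_field")) stop("'field' must be a normal_field")
  n <- nrow(pts)
  if (nrow(field$normals) != n)
    stop("normal field and cloud have different sizes")
  nb <- knn(pts, min(params$k, n))
  cos_thr <- cos(deg2rad(params$theta_smooth))
  assigned <- rep(FALSE, n)
  region_of <- integer(n)
  # invalid normals can never satisfy the smoothness test; straight to noise
  assigned[!field$valid] <- TRUE

  seed_order <- order(field$curvatures, seq_len(n))
  segments <- list()
  for (s in seed_order) {
    if (assigned[s]) next
    region <- integer(0)
    queue <- s
    head <- 1L
    assigned[s] <- TRUE
    seed_normal <- field$normals[s, ]
    while (head <= length(queue)) {
      p <- queue[[head]]
      head <- head + 1L
      region <- c(region, p)
      cand <- nb[p, ]
      cand <- cand[!assigned[cand]]
      if (length(cand)) {
        cosang <- abs(drop(field$normals[cand, , drop = FALSE] %*% seed_normal))
        join <- cand[cosang >= cos_thr]
        if (length(join)) {
          assigned[join] <- TRUE
          grow <- join[field$curvatures[join] <= params$c_max]
          region <- c(region, setdiff(join, grow))
          queue <- c(queue, grow)
        }
      }
    }
    region <- sort(unique(region))
    if (length(region) >= params$min_size) {
      segments[[length(segments) + 1L]] <- region
      region_of[region] <- length(segments)
    }
  }
  seg_pts <- unlist(segments)
  noise <- setdiff(seq_len(n), seg_pts)
  if (length(segments)) {
    ord <- order(-lengths(segments), vapply(segments, min, integer(1)))
    segments <- segments[ord]
  }
  structure(list(segments = segments, noise = sort(noise), params = params,
                 n_points = n),
            class = "leaf_segmentation")
}

#' @export
print.leaf_segmentation <- function(x, ...) {
  cat(sprintf("<leaf_segmentation> %d segment(s) over %d points, %d noise\n",
              length(x$segments), x$n_points, length(x$noise)))
  if (length(x$segments))
    cat("  sizes:", paste(lengths(x$segments), collapse = ", "), "\n")
  invisible(x)
}

#' Score a segmentation against ground-truth labels
#'
#' Point-level precision and recall of the leaf-vs-noise decision, plus the
#' number of predicted segments attributed to each true leaf by majority
#' vote of their points' labels. A per-leaf count above 1 means the leaf was
#' split into several probing regions (expected on strongly twisted
#' leaves); a count of 0 means it was missed.
#'
#' @param pred `leaf_segmentation`
#' @param truth `labeled_cloud` with ground-truth labels on the same points
#' @return list with `precision`, `recall`, `per_leaf_segments` (named
#'   integer vector over true leaf ids), `n_segments`
#' @export
segmentation_quality <- function(pred, truth) {
  stopifnot(inherits(pred, "leaf_segmentation"), inherits(truth, "labeled_cloud"))
  if (pred$n_points != nrow(truth$points))
    stop("segmentation and truth refer to different clouds")
  pred_leaf <- unlist(pred$segments)
  true_leaf <- which(truth$labels > 0L)
  tp <- length(intersect(pred_leaf, true_leaf))
  precision <- if (length(pred_leaf)) tp / length(pred_leaf) else NA_real_
  recall <- if (length(true_leaf)) tp / length(true_leaf) else NA_real_
  ids <- sort(setdiff(unique(truth$labels), 0L))
  counts <- stats::setNames(integer(length(ids)), ids)
  for (seg in pred$segments) {
    labs <- truth$labels[seg]
    labs <- labs[labs > 0L]
    if (!length(labs)) next
    tab <- table(labs)
    maj <- names(tab)[which.max(tab)]
    counts[maj] <- counts[maj] + 1L
  }
  list(precision = precision, recall = recall, per_leaf_segments = counts,
       n_segments = length(pred$segments))
}
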