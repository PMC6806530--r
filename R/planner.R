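# Probing-site selection and sensor pose planning. The geometric constants
# mirror the facility's operating numbers: fluorometer probe 8 mm from the
# leaf at a 60 degree angle to the surface, hyperspectral slices 5 mm wide
# imaged from 0.25 m, a 0.5 x 0.5 m top-view footprint, and a 1.3 m arm
# reach radius.

#' Workspace model of the rover arm
#'
#' @param arm_base arm base position, m
#' @param reach_radius maximum reach of the arm, m (default 1.3)
#' @param probe_clearance_radius swept-cylinder radius used for collision
#'   checks along the probe approach, mm
#' @return object of class `workspace_model`
#' @export
workspace_model <- function(arm_base = c(0, 0, 0), reach_radius = 1.3,
                            probe_clearance_radius = 15) {
  if (reach_radius <= 0) stop("'reach_radius' must be positive")
  structure(list(arm_base = as.numeric(arm_base), reach_radius = reach_radius,
                 probe_clearance_radius = probe_clearance_radius),
            class = "workspace_model")
}

# Largest inscribed flat neighborhood radius around a candidate site: the
# biggest radius (from a geometric grid of trial radii) at which (a) the
# in-radius points fit a plane with RMS residual <= tol_mm and (b) the
# radius-r disk is fully populated with segment points (count at least 60%
# of the density-expected count, so rim points score low and interior
# points high -- the probe must land on leaf interior).
flat_radius_score <- function(site_idx, pts, cand_pts, tol_mm = 1,
                              r_unit = NULL) {
  d <- sqrt(rowSums(sweep(cand_pts, 2, pts[site_idx, ])^2))
  r_max <- max(d)
  if (r_max <= 0) return(0)
  if (is.null(r_unit)) r_unit <- sort(d)[min(9, length(d))]
  if (r_unit <= 0) return(0)
  radii <- r_max * (0.75^(seq_len(14) - 1))
  best <- 0
  for (r in sort(radii)) {
    n_in <- sum(d <= r)
    if (n_in < 3) next
    expected <- 8 * (r / r_unit)^2
    if (n_in < 0.6 * expected) break
    sel <- cand_pts[d <= r, , drop = FALSE]
    ctr <- sweep(sel, 2, colMeans(sel))
    ev <- eigen(crossprod(ctr) / nrow(sel), symmetric = TRUE, only.values = TRUE)$values
    rms <- sqrt(max(ev[3], 0))
    if (m2mm(rms) <= tol_mm) best <- r else break
  }
  best
}

#' Select probing sites on leaf segments
#'
#' Candidate sites are scored by the radius of the largest inscribed
#' neighborhood around them whose points fit a plane within a 1 mm RMS
#' flatness tolerance and fully cover the neighborhood disk (so a site at a
#' flat segment's center outranks its rim) — the "large, smooth portion"
#' of a leaf. Sites are allocated
#' one per segment (best first) until every segment has one, then
#' round-robin by score.
#'
#' @param seg `leaf_segmentation`
#' @param cloud `labeled_cloud` or N x 3 matrix the segmentation refers to
#' @param field `normal_field` on the same points
#' @param n_sites maximum number of sites to return (the facility's probing
#'   runs typically use 4 per plant)
#' @param flatness_tol_mm RMS plane-fit tolerance, mm
#' @param max_candidates per-segment cap on scored candidates (uniform
#'   index subsample; keeps the exhaustive scorer tractable)
#' @return data.frame with columns segment, index, x, y, z, nx, ny, nz,
#'   score (flat radius, m), ordered as allocated
#' @export
select_probe_sites <- function(seg, cloud, field, n_sites = 4L,
                               flatness_tol_mm = 1, max_candidates = 250L) {
  pts <- if (inherits(cloud, "labeled_cloud")) cloud$points else as_points(cloud)
  empty <- data.frame(segment = integer(0), index = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      nx = numeric(0), ny = numeric(0), nz = numeric(0),
                      score = numeric(0))
  if (!length(seg$segments)) return(empty)
  per_seg <- vector("list", length(seg$segments))
  for (si in seq_along(seg$segments)) {
    idx <- seg$segments[[si]]
    cand_pts <- pts[idx, , drop = FALSE]
    cand <- idx
    if (length(cand) > max_candidates) {
      step <- ceiling(length(cand) / max_candidates)
      cand <- cand[seq(1L, length(cand), by = step)]
    }
    # segment-wide sampling unit: median 9th-nearest distance (interior
    # spacing); a per-candidate unit would under-count density at rims and
    # defeat the coverage test
    d9 <- vapply(cand, function(i) {
      d <- sqrt(rowSums(sweep(cand_pts, 2, pts[i, ])^2))
      sort(d)[min(9, length(d))]
    }, numeric(1))
    r_unit <- stats::median(d9)
    scores <- vapply(cand, function(i) {
      flat_radius_score(i, pts, cand_pts, tol_mm = flatness_tol_mm,
                        r_unit = r_unit)
    }, numeric(1))
    o <- order(-scores, cand)
    per_seg[[si]] <- data.frame(segment = si, index = cand[o],
                                score = scores[o])
  }
  # allocation: round-robin over segments, each round takes every segment's
  # next-best site; segments ordered by their best score
  seg_order <- order(-vapply(per_seg, function(d) d$score[1], numeric(1)))
  picked <- list()
  round <- 1L
  while (length(picked) < n_sites) {
    any_new <- FALSE
    for (si in seg_order) {
      if (length(picked) >= n_sites) break
      d <- per_seg[[si]]
      if (nrow(d) >= round) {
        picked[[length(picked) + 1L]] <- d[round, ]
        any_new <- TRUE
      }
    }
    if (!any_new) break
    round <- round + 1L
  }
  out <- do.call(rbind, picked)
  out <- cbind(out[, c("segment", "index")],
               x = pts[out$index, 1], y = pts[out$index, 2], z = pts[out$index, 3],
               nx = field$normals[out$index, 1], ny = field$normals[out$index, 2],
               nz = field$normals[out$index, 3],
               score = out$score)
  rownames(out) <- NULL
  out
}

#' Compute a probe pose from a site and its surface normal
#'
#' The probe axis points from the probe tip toward the target and makes the
#' requested incidence angle with the leaf tangent plane (so 90 degrees is
#' perpendicular probing, and the default 60 degrees with an 8 mm standoff
#' reproduces the fluorometer leaf-clip geometry). The tilt azimuth — which
#' tangent direction the axis leans toward — is resolved deterministically
#' from `azimuth_hint` projected onto the tangent plane.
#'
#' @param site length-3 target point on the leaf, m
#' @param normal unit surface normal at the site
#' @param standoff_mm probe tip to target distance, mm (default 8)
#' @param incidence_deg angle between probe axis and tangent plane, degrees
#'   in (0, 90] (default 60)
#' @param azimuth_hint direction whose tangent-plane projection fixes the
#'   tilt azimuth; ignored at 90 degree incidence
#' @return object of class `probe_pose`: `target`, `axis` (unit, from tip
#'   toward target), `tip`, `standoff_mm`, `incidence_deg`
#' @export
compute_probe_pose <- function(site, normal, standoff_mm = 8, incidence_deg = 60,
                               azimuth_hint = c(1, 0, 0)) {
  if (incidence_deg <= 0 || incidence_deg > 90)
    stop("'incidence_deg' must lie in (0, 90]")
  if (standoff_mm <= 0) stop("'standoff_mm' must be positive")
  normal <- as.numeric(normal)
  if (abs(vnorm(normal) - 1) > 1e-6) stop("'normal' must be a unit vector")
  site <- as.numeric(site)
  if (incidence_deg == 90) {
    axis <- normal
  } else {
    t_raw <- azimuth_hint - sum(azimuth_hint * normal) * normal
    if (vnorm(t_raw) < 1e-9) {
      # hint parallel to normal: fall back to a canonical tangent
      for (e in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
        t_raw <- e - sum(e * normal) * normal
        if (vnorm(t_raw) >= 1e-9) break
      }
    }
    t_hat <- unitize(t_raw)
    a <- deg2rad(incidence_deg)
    axis <- sin(a) * normal + cos(a) * t_hat
    axis <- unitize(axis)
  }
  tip <- site - mm2m(standoff_mm) * axis
  structure(list(target = site, axis = axis, tip = tip,
                 standoff_mm = standoff_mm, incidence_deg = incidence_deg),
            class = "probe_pose")
}

#' @export
print.probe_pose <- function(x, ...) {
  cat(sprintf("<probe_pose> target (%.3f, %.3f, %.3f) m, standoff %g mm, incidence %g deg\n",
              x$target[1], x$target[2], x$target[3], x$standoff_mm, x$incidence_deg))
  invisible(x)
}

#' Check reachability and collision freedom of a probe pose
#'
#' A pose is infeasible if the probe tip lies beyond the arm's reach radius
#' ("unreachable") or if any obstacle point intrudes into the cylinder of
#' radius `ws$probe_clearance_radius` swept along the approach axis from tip
#' to target ("collision"). Points belonging to the probed surface itself
#' are excluded via `exclude` (typically the target's local neighborhood /
#' slice); this is a straight-approach check, not full arm path planning.
#'
#' @param pose `probe_pose`
#' @param cloud obstacle cloud (`labeled_cloud` or matrix)
#' @param ws `workspace_model`
#' @param exclude integer indices of cloud points to ignore (the target
#'   surface); by default, points within 2 standoffs of the target
#' @return list with `feasible` (logical) and `reason` (`"ok"`,
#'   `"unreachable"` or `"collision"`)
#' @export
check_feasible <- function(pose, cloud, ws, exclude = NULL) {
  stopifnot(inherits(pose, "probe_pose"), inherits(ws, "workspace_model"))
  if (vnorm(pose$tip - ws$arm_base) > ws$reach_radius)
    return(list(feasible = FALSE, reason = "unreachable"))
  pts <- if (inherits(cloud, "labeled_cloud")) cloud$points else as_points(cloud)
  if (nrow(pts)) {
    if (is.null(exclude)) {
      d_t <- sqrt(rowSums(sweep(pts, 2, pose$target)^2))
      exclude <- which(d_t <= 2 * mm2m(pose$standoff_mm))
    }
    if (length(exclude)) pts <- pts[-exclude, , drop = FALSE]
  }
  if (nrow(pts)) {
    rel <- sweep(pts, 2, pose$tip)
    L <- mm2m(pose$standoff_mm)
    t_along <- drop(rel %*% pose$axis)
    in_span <- t_along >= 0 & t_along <= L
    if (any(in_span)) {
      perp2 <- rowSums(rel[in_span, , drop = FALSE]^2) - t_along[in_span]^2
      if (any(perp2 <= mm2m(ws$probe_clearance_radius)^2))
        return(list(feasible = FALSE, reason = "collision"))
    }
  }
  list(feasible = TRUE, reason = "ok")
}

#' Dissect a leaf segment into slices along its major axis
#'
#' Points are binned by their projection onto the segment's major principal
#' axis into contiguous `slice_width_mm` bins starting at the minimum
#' projection; the number of slices is ceiling(extent / width), so the last
#' slice may be narrower. Empty bins are kept as empty slices so the slice
#' index maps linearly to position along the leaf.
#'
#' @param points M x 3 segment points, M >= 3
#' @param slice_width_mm slice width, mm (default 5, the facility's value)
#' @return object of class `slice_plan`: `slices` (list of
#'   `list(indices, interval_mm)`), `slice_width_mm`, `axes`
#'   (from [principal_axes()]), `extent_mm`, `scan_poses` (NULL until
#'   [plan_line_scan_poses()])
#' @export
slice_leaf <- function(points, slice_width_mm = 5) {
  points <- as_points(points)
  if (slice_width_mm <= 0) stop("'slice_width_mm' must be positive")
  ax <- principal_axes(points)
  proj <- m2mm(drop(sweep(points, 2, ax$centroid) %*% ax$axes[, 1]))
  proj <- proj - min(proj)
  extent <- max(proj)
  n_slices <- if (extent == 0) 1L else as.integer(ceiling(extent / slice_width_mm))
  slices <- vector("list", n_slices)
  bin <- pmin(floor(proj / slice_width_mm) + 1L, n_slices)
  for (b in seq_len(n_slices)) {
    lo <- (b - 1) * slice_width_mm
    hi <- min(b * slice_width_mm, max(extent, slice_width_mm * (extent == 0)))
    if (extent == 0) hi <- 0
    slices[[b]] <- list(indices = which(bin == b), interval_mm = c(lo, hi))
  }
  if (extent > 0) slices[[n_slices]]$interval_mm[2] <- extent
  structure(list(slices = slices, slice_width_mm = slice_width_mm,
                 axes = ax, extent_mm = extent, scan_poses = NULL,
                 points = points),
            class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat(sprintf("<slice_plan> %d slice(s) of %g mm over %.1f mm extent%s\n",
              length(x$slices), x$slice_width_mm, x$extent_mm,
              if (is.null(x$scan_poses)) "" else ", scan poses planned"))
  invisible(x)
}

#' Plan hyperspectral line-scan camera poses per slice
#'
#' For each slice with at least 3 points the camera center is placed at the
#' slice centroid plus `working_distance` along the mean slice normal
#' (default 0.25 m, the leaf-tracing scan distance), viewing down the
#' normal; the scan line direction is the segment major axis projected onto
#' the image plane, i.e. the sensor scans as parallel to the slice surface
#' as possible. Slices with fewer than 3 points inherit the pose of the
#' nearest planned slice.
#'
#' @param plan `slice_plan`
#' @param field `normal_field` over the cloud the slice indices refer to,
#'   or NULL to use per-slice plane fits oriented upward
#' @param working_distance camera-to-centroid distance, m (default 0.25)
#' @return the `slice_plan` with `scan_poses`: per slice a list with
#'   `camera` (position), `view_axis` (unit, camera toward slice),
#'   `scan_dir` (unit, in the image plane), `centroid`, `inherited_from`
#'   (NA or donor slice index)
#' @export
plan_line_scan_poses <- function(plan, field = NULL, working_distance = 0.25) {
  stopifnot(inherits(plan, "slice_plan"))
  if (!length(plan$slices)) stop("slice plan has no slices")
  major <- plan$axes$axes[, 1]
  poses <- vector("list", length(plan$slices))
  planned <- logical(length(plan$slices))
  for (b in seq_along(plan$slices)) {
    idx <- plan$slices[[b]]$indices
    if (length(idx) < 3) next
    sl_pts <- plan$points[idx, , drop = FALSE]
    ctr <- colMeans(sl_pts)
    if (!is.null(field)) {
      nrm_raw <- colMeans(field$normals[idx, , drop = FALSE], na.rm = TRUE)
    } else {
      ev <- eigen(crossprod(sweep(sl_pts, 2, ctr)) / length(idx), symmetric = TRUE)
      nrm_raw <- ev$vectors[, 3]
      if (nrm_raw[3] < 0) nrm_raw <- -nrm_raw
    }
    nrm <- unitize(nrm_raw)
    cam <- ctr + working_distance * nrm
    view <- -nrm
    sd_raw <- major - sum(major * view) * view
    scan_dir <- if (vnorm(sd_raw) < 1e-9) canonical_sign(plan$axes$axes[, 2]) else unitize(sd_raw)
    poses[[b]] <- list(camera = cam, view_axis = view, scan_dir = scan_dir,
                       centroid = ctr, inherited_from = NA_integer_)
    planned[b] <- TRUE
  }
  if (!any(planned)) stop("no slice has >= 3 points; cannot plan scan poses")
  donors <- which(planned)
  for (b in which(!planned)) {
    d <- donors[which.min(abs(donors - b))]
    poses[[b]] <- poses[[d]]
    poses[[b]]$inherited_from <- d
  }
  plan$scan_poses <- poses
  plan$working_distance <- working_distance
  plan
}

#' Top-view camera pose covering a square footprint
#'
#' Places the camera on the vertical axis above the plant so that the
#' narrower field-of-view subtends at least `footprint_side` at the plant
#' height: standoff = footprint_side / (2 tan(fov_min / 2)). With the ToF
#' camera's 43 x 33 degree FOV and the standard 0.5 m footprint this puts
#' the camera 0.844 m above the plant (0.635 m for the 43 degree axis
#' alone; the 33 degree axis governs).
#'
#' @param plant_height plant height, m
#' @param camera_fov length-2 FOV (degrees); the smaller entry governs
#' @param footprint_side side of the square imaging area at plant height, m
#'   (default 0.5)
#' @param plant_center xy position of the plant, m
#' @return list with `camera` (position), `look_at`, `standoff` (height
#'   above the plant, m), `footprint_side`
#' @export
plan_topview_pose <- function(plant_height, camera_fov = c(43, 33),
                              footprint_side = 0.5, plant_center = c(0, 0)) {
  if (any(camera_fov <= 0) || any(camera_fov >= 180))
    stop("'camera_fov' angles must lie in (0, 180)")
  fov_min <- min(camera_fov)
  standoff <- footprint_side / (2 * tan(deg2rad(fov_min) / 2))
  cam <- c(plant_center[1], plant_center[2], plant_height + standoff)
  list(camera = cam, look_at = c(plant_center[1], plant_center[2], plant_height),
       standoff = standoff, footprint_side = footprint_side)
}
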