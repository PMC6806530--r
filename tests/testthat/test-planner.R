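test_that("probe pose satisfies standoff and incidence exactly", {
  # closed-form case: horizontal surface, 60 deg incidence tilted toward +x
  p <- compute_probe_pose(c(0, 0, 0), c(0, 0, 1), 8, 60, azimuth_hint = c(1, 0, 0))
  expect_equal(p$axis, c(0.5, 0, sqrt(3) / 2), tolerance = 1e-9)
  expect_equal(p$tip * 1000, c(-4, 0, -4 * sqrt(3)), tolerance = 1e-6)

  # 90 degrees: perpendicular probing along the normal
  p90 <- compute_probe_pose(c(0.1, 0.2, 0.3), c(0, 1, 0), 8, 90)
  expect_equal(p90$axis, c(0, 1, 0))

  # generic poses: |tip - target| = standoff and incidence to 1e-9
  set.seed(3)
  for (i in 1:20) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    hint <- rnorm(3)
    inc <- runif(1, 5, 90)
    so <- runif(1, 2, 20)
    pp <- compute_probe_pose(rnorm(3), n, so, inc, azimuth_hint = hint)
    expect_equal(sqrt(sum((pp$tip - pp$target)^2)) * 1000, so, tolerance = 1e-9)
    got_inc <- 90 - acos(abs(sum(pp$axis * n))) * 180 / pi
    expect_equal(got_inc, inc, tolerance = 1e-7)
  }

  # equivariance under rotation
  R <- random_rotation(5)
  base <- compute_probe_pose(c(0.1, 0, 0.2), c(0, 0, 1), 8, 60, c(1, 0, 0))
  rot <- compute_probe_pose(drop(R %*% c(0.1, 0, 0.2)), drop(R %*% c(0, 0, 1)),
                            8, 60, drop(R %*% c(1, 0, 0)))
  expect_equal(rot$axis, drop(R %*% base$axis), tolerance = 1e-9)
  expect_equal(rot$tip, drop(R %*% base$tip), tolerance = 1e-9)

  expect_error(compute_probe_pose(c(0, 0, 0), c(0, 0, 1), 8, 0), "incidence")
  expect_error(compute_probe_pose(c(0, 0, 0), c(0, 0, 1), 8, 95), "incidence")
})

test_that("site selection puts the site at a flat disk's center", {
  # uniform-pitch disk: the inscribed flat radius is disk_radius - |site|,
  # analytically maximized at the center
  g <- expand.grid(x = seq(-0.05, 0.05, by = 0.004),
                   y = seq(-0.05, 0.05, by = 0.004))
  keep <- g$x^2 + g$y^2 <= 0.05^2
  disk <- cbind(g$x[keep], g$y[keep], 0)
  field <- estimate_normals_curvature(disk, k = 8, view_origin = c(0, 0, 1))
  seg <- structure(list(segments = list(seq_len(nrow(disk))), noise = integer(0),
                        params = segmentation_params(min_size = 3),
                        n_points = nrow(disk)),
                   class = "leaf_segmentation")
  sites <- select_probe_sites(seg, disk, field, n_sites = 1,
                              max_candidates = 1000)
  expect_equal(nrow(sites), 1)
  expect_lt(sqrt(sites$x^2 + sites$y^2), 0.01)  # well inside, near center
  expect_gt(sites$score, 0.03)  # a large fraction of the 0.05 disk radius

  # empty segmentation -> no sites
  eseg <- structure(list(segments = list(), noise = seq_len(nrow(disk)),
                         params = segmentation_params(), n_points = nrow(disk)),
                    class = "leaf_segmentation")
  expect_equal(nrow(select_probe_sites(eseg, disk, field, 4)), 0)
})

test_that("sites spread across segments before round-robin", {
  rib <- leaf_model("elongated_twisted", 300, 40, twist_rate = 0.45,
                    attachment = c(0, 0, 0.5), inclination = 10)
  rpts <- leaf_surface_points(rib, pitch_mm = 3)
  field <- estimate_normals_curvature(rpts, k = 10, view_origin = c(0.15, 0, 1.5))
  seg <- region_grow(rpts, field, segmentation_params(25, 0.05, 60, 10))
  expect_gte(length(seg$segments), 2)
  sites <- select_probe_sites(seg, rpts, field, n_sites = 4)
  expect_gte(length(unique(sites$segment)), 2)
  # one site per segment before any segment gets its second
  first_round <- sites$segment[seq_len(min(nrow(sites), length(seg$segments)))]
  expect_equal(anyDuplicated(first_round), 0)
})

test_that("feasibility verdicts: unreachable, clear, collision, monotone", {
  ws <- workspace_model(arm_base = c(0, 0, 0), reach_radius = 1.3)
  far <- compute_probe_pose(c(1.4, 0, 0), c(0, 0, 1), 8, 60)
  v <- check_feasible(far, matrix(numeric(0), 0, 3), ws)
  expect_false(v$feasible)
  expect_equal(v$reason, "unreachable")

  near <- compute_probe_pose(c(0.5, 0, 0.3), c(0, 0, 1), 8, 90)
  v2 <- check_feasible(near, matrix(numeric(0), 0, 3), ws)
  expect_true(v2$feasible)

  # an obstacle point dropped onto the approach axis midway tip->target
  mid <- near$tip + 0.5 * (near$target - near$tip)
  obst <- rbind(mid + c(0.001, 0, 0))
  v3 <- check_feasible(near, obst, ws, exclude = integer(0))
  expect_false(v3$feasible)
  expect_equal(v3$reason, "collision")
  # the same point just outside the clearance cylinder is fine
  obst2 <- rbind(mid + c(0.02, 0, 0))  # 20 mm > 15 mm clearance
  expect_true(check_feasible(near, obst2, ws, exclude = integer(0))$feasible)

  # shrinking reach never turns infeasible poses feasible
  radii <- c(2, 1.3, 0.8, 0.4, 0.2)
  feas <- sapply(radii, function(r) {
    check_feasible(near, obst2, workspace_model(c(0, 0, 0), r),
                   exclude = integer(0))$feasible
  })
  expect_true(all(diff(feas) <= 0))
})

test_that("slice counts follow ceiling(extent / width) with exact tiling", {
  mk_ribbon <- function(len_m) {
    g <- expand.grid(x = seq(0, len_m, by = 0.001), y = seq(0, 0.02, by = 0.002))
    cbind(g$x, g$y, 0)
  }
  p100 <- mk_ribbon(0.100)
  s100 <- slice_leaf(p100, 5)
  expect_length(s100$slices, 20)

  p101 <- mk_ribbon(0.101)
  s101 <- slice_leaf(p101, 5)
  expect_length(s101$slices, 21)
  expect_equal(diff(s101$slices[[21]]$interval_mm), 1, tolerance = 1e-6)

  # degenerate: extent below one width -> single slice
  g <- expand.grid(x = seq(0, 0.004, by = 0.001), y = seq(0, 0.004, by = 0.001))
  s1 <- slice_leaf(cbind(g$x, g$y, 0), 5)
  expect_length(s1$slices, 1)

  # tiling invariant: intervals cover [0, extent] without overlap, interior
  # widths all equal the slice width; every point in exactly one slice
  for (s in list(s100, s101)) {
    iv <- t(sapply(s$slices, `[[`, "interval_mm"))
    expect_equal(iv[1, 1], 0)
    expect_equal(iv[nrow(iv), 2], s$extent_mm, tolerance = 1e-9)
    expect_true(all(abs(iv[-1, 1] - iv[-nrow(iv), 2]) < 1e-9))
    expect_true(all(abs(diff(t(iv))[seq_len(nrow(iv) - 1)] - s$slice_width_mm) < 1e-9))
    counts <- lengths(lapply(s$slices, `[[`, "indices"))
    expect_equal(sum(counts), nrow(s$points))
  }

  expect_error(slice_leaf(p100, 0), "positive")
})

test_that("line-scan poses sit at the working distance along slice normals", {
  g <- expand.grid(x = seq(0, 0.1, by = 0.002), y = seq(0, 0.02, by = 0.002))
  flat <- cbind(g$x, g$y, 0.4)
  plan <- slice_leaf(flat, 5)
  plan <- plan_line_scan_poses(plan, working_distance = 0.25)
  for (sp in plan$scan_poses) {
    expect_equal(sqrt(sum((sp$camera - sp$centroid)^2)), 0.25, tolerance = 1e-12)
  }
  # horizontal slice: camera directly above the centroid
  sp1 <- plan$scan_poses[[1]]
  expect_equal(sp1$camera[1:2], sp1$centroid[1:2], tolerance = 1e-9)
  expect_equal(sp1$camera[3], 0.4 + 0.25, tolerance = 1e-9)
  # scan direction lies in the image plane and along the leaf
  expect_lt(abs(sum(sp1$scan_dir * sp1$view_axis)), 1e-9)
  expect_gt(abs(sp1$scan_dir[1]), 1 - 1e-9)

  # equivariance: rotating the leaf rotates the camera poses. The sign
  # convention on the major axis may reverse slice order under rotation, so
  # the fixture has an exact-multiple extent (100 mm) and keeps every
  # interior point well away from slice boundaries, making the reversal an
  # exact bin permutation.
  p_mm <- seq(0.25, 99.75, by = 0.5)
  p_mm <- p_mm[pmin(p_mm %% 5, 5 - p_mm %% 5) > 0.1]
  xs <- c(0, p_mm, 100) / 1000
  g2 <- expand.grid(x = xs, y = seq(0, 0.02, by = 0.005))
  flat2 <- cbind(g2$x, g2$y, 0.4)
  plan2 <- plan_line_scan_poses(slice_leaf(flat2, 5), working_distance = 0.25)
  R <- random_rotation(11)
  planR <- plan_line_scan_poses(slice_leaf(flat2 %*% t(R), 5),
                                working_distance = 0.25)
  flip <- sum(drop(R %*% plan2$axes$axes[, 1]) * planR$axes$axes[, 1]) < 0
  nb <- length(plan2$scan_poses)
  expect_equal(length(planR$scan_poses), nb)
  for (b in seq_len(nb)) {
    a <- plan2$scan_poses[[b]]
    r <- planR$scan_poses[[if (flip) nb + 1 - b else b]]
    expect_equal(r$centroid, drop(R %*% a$centroid), tolerance = 1e-9)
    expect_equal(abs(sum(r$view_axis * drop(R %*% a$view_axis))), 1, tolerance = 1e-9)
  }
})

test_that("thin slices inherit poses from the nearest planned slice", {
  # 3 x 5 mm of dense points then a lone far point -> middle slices empty
  g <- expand.grid(x = seq(0, 0.014, by = 0.001), y = seq(0, 0.01, by = 0.002))
  pts <- rbind(cbind(g$x, g$y, 0), c(0.040, 0.005, 0))
  plan <- plan_line_scan_poses(slice_leaf(pts, 5))
  expect_length(plan$slices, 8)
  inh <- sapply(plan$scan_poses, function(s) s$inherited_from)
  expect_true(any(!is.na(inh)))           # the empty/thin slices inherited
  expect_true(all(!is.na(sapply(plan$scan_poses, function(s) s$camera[1]))))
})

test_that("top-view standoff follows the footprint / FOV relation", {
  tv <- plan_topview_pose(0.5, c(43, 43), 0.5)
  expect_equal(tv$standoff, 0.25 / tan(21.5 * pi / 180), tolerance = 1e-9)
  expect_equal(tv$standoff, 0.635, tolerance = 1e-3)
  # the narrower FOV governs
  tv2 <- plan_topview_pose(0.5, c(43, 33), 0.5)
  expect_equal(tv2$standoff, 0.25 / tan(16.5 * pi / 180), tolerance = 1e-9)
  # linearity in footprint; zero-footprint limit
  expect_equal(plan_topview_pose(0.5, c(43, 43), 1.0)$standoff, 2 * tv$standoff)
  expect_lt(plan_topview_pose(0.5, c(43, 43), 1e-9)$standoff, 1e-8)
  expect_error(plan_topview_pose(0.5, c(0, 43), 0.5), "0, 180")
})
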