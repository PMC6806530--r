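# Fixtures are all built in code: geometric point sets with known ground
# truth, plus oracle implementations kept deliberately naive.

# regular grid on the z = 0 plane, extents in meters
plane_cloud <- function(nx = 20, ny = 20, dx = 0.005, z = 0, x0 = 0, y0 = 0) {
  g <- expand.grid(x = x0 + (seq_len(nx) - 1) * dx,
                   y = y0 + (seq_len(ny) - 1) * dx)
  cbind(g$x, g$y, z)
}

# deterministic quasi-uniform points on a sphere (Fibonacci lattice)
sphere_cloud <- function(n = 500, r = 0.1, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + r * sin(phi) * cos(theta),
        center[2] + r * sin(phi) * sin(theta),
        center[3] + r * cos(phi))
}

# two planes meeting at a crease along the y axis with a given dihedral
# normal difference (degrees); each wing extends `len` m from the crease
crease_cloud <- function(angle_deg = 90, len = 0.1, pitch = 0.002) {
  s <- seq(pitch, len, by = pitch)
  y <- seq(0, len, by = pitch)
  g1 <- expand.grid(s = s, y = y)
  wing1 <- cbind(-g1$s, g1$y, 0)
  a <- pi * angle_deg / 180
  g2 <- expand.grid(s = s, y = y)
  wing2 <- cbind(g2$s * cos(a), g2$y, -g2$s * sin(a))
  list(points = rbind(wing1, wing2),
       wing = rep(1:2, c(nrow(wing1), nrow(wing2))),
       dist_to_crease = c(g1$s, g2$s),
       normal1 = c(0, 0, 1),
       normal2 = c(sin(a), 0, cos(a)))
}

# brute-force O(N^2) knn oracle, ties by index
knn_oracle <- function(points, k) {
  n <- nrow(points)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(points) - points[i, ])^2))
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a one-leaf scene with controlled leaf geometry
single_leaf_scene <- function(style = "flat_round", length_mm = 120,
                              width_mm = 90, twist_rate = 0,
                              inclination = 0, seed = 1) {
  scene <- build_scene(scene_spec(1, style), seed = seed)
  lf <- leaf_model(style, length_mm, width_mm, twist_rate,
                   attachment = c(0.6, 0.6, 0.5), azimuth = 0,
                   inclination = inclination)
  lf$leaf_id <- 1L
  scene$pots[[1]]$leaves <- list(lf)
  scene$pots[[1]]$position <- c(0.6, 0.6)
  scene$n_leaves <- 1L
  scene
}

# normal field + segmentation in one call with sensible defaults
segment_points <- function(pts, theta = 10, c_max = 0.05, min_size = 100,
                           k = 10, view = NULL) {
  if (is.null(view))
    view <- c(mean(pts[, 1]), mean(pts[, 2]), max(pts[, 3]) + 1)
  field <- estimate_normals_curvature(pts, k = k, view_origin = view)
  region_grow(pts, field, segmentation_params(theta, c_max, min_size, k))
}

# pixel-counting oracle for region means
region_mean_oracle <- function(values, shape) {
  H <- nrow(values); W <- ncol(values)
  acc <- c(); n <- 0L
  for (y in seq_len(H)) for (x in seq_len(W)) {
    inside <- if (shape$kind == "circle") {
      (x - shape$cx)^2 + (y - shape$cy)^2 <= shape$radius^2
    } else {
      v <- shape$p2 - shape$p1
      t_par <- ((x - shape$p1[1]) * v[1] + (y - shape$p1[2]) * v[2]) / sum(v^2)
      t_cl <- min(max(t_par, 0), 1)
      (x - (shape$p1[1] + t_cl * v[1]))^2 +
        (y - (shape$p1[2] + t_cl * v[2]))^2 <= (shape$thickness / 2)^2
    }
    if (inside) { acc <- c(acc, values[y, x]); n <- n + 1L }
  }
  list(mean = mean(acc), n = n)
}
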