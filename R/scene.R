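# Synthetic chamber scenes: parametric plants, two-fidelity labeled point
# clouds, and hyperspectral/thermal fixtures. Everything downstream
# (segmentation, planning, measurement) is testable against these without
# any external data.
#
# Conventions: right-handed frame, z-up, chamber floor at z = 0; meters
# internally, millimeters at config boundaries (leaf dimensions, sensor
# noise and pitch).

#' Parametric leaf model
#'
#' Two leaf styles span the geometric contrast that drives segmentation
#' behavior: `flat_round` is an elliptical planar disk (a soybean-like
#' leaflet, small, flat and round, so a leaf segment is typically the whole
#' leaf); `elongated_twisted` is a ruled ribbon whose cross-section rotates
#' about the major axis at `twist_rate` (a maize-like leaf, on which several
#' distinct smooth probing regions exist).
#'
#' @param species_style `"flat_round"` or `"elongated_twisted"`
#' @param length_mm,width_mm leaf dimensions in millimeters
#' @param twist_rate degrees of cross-section rotation per mm along the
#'   major axis; must be 0 for `flat_round`
#' @param attachment length-3 world attachment point of the leaf base, m
#' @param azimuth,inclination leaf major-axis direction: azimuth about z
#'   (degrees, from +x), inclination above the horizontal (degrees)
#' @return object of class `leaf_model`
#' @export
leaf_model <- function(species_style = c("flat_round", "elongated_twisted"),
                       length_mm, width_mm, twist_rate = 0,
                       attachment = c(0, 0, 0.3), azimuth = 0, inclination = 20) {
  species_style <- match.arg(species_style)
  if (length_mm <= 0 || width_mm <= 0) stop("leaf length and width must be positive")
  if (species_style == "flat_round" && twist_rate != 0)
    stop("a flat_round leaf must have twist_rate = 0")
  structure(list(species_style = species_style, length_mm = length_mm,
                 width_mm = width_mm, twist_rate = twist_rate,
                 attachment = as.numeric(attachment),
                 azimuth = azimuth, inclination = inclination),
            class = "leaf_model")
}

# Leaf local frame -> world rotation (x = major axis).
leaf_rotation <- function(leaf) rot_z(leaf$azimuth) %*% rot_y(-leaf$inclination)

# Elliptical half-width profile at arclength s (mm).
leaf_half_width <- function(leaf, s) {
  u <- 2 * s / leaf$length_mm - 1
  (leaf$width_mm / 2) * sqrt(pmax(0, 1 - u^2))
}

#' Sample points on a leaf's parametric surface
#'
#' Deterministic grid sampling at approximately `pitch_mm` spacing along and
#' across the leaf. Used by the cloud sampler and the fixture rasterizer.
#'
#' @param leaf a `leaf_model`
#' @param pitch_mm target sample spacing in millimeters
#' @return matrix of world coordinates (m)
#' @export
leaf_surface_points <- function(leaf, pitch_mm = 2) {
  if (pitch_mm <= 0) stop("'pitch_mm' must be positive")
  R <- leaf_rotation(leaf)
  s_vals <- seq(0, leaf$length_mm, by = pitch_mm)
  pts <- vector("list", length(s_vals))
  for (j in seq_along(s_vals)) {
    s <- s_vals[j]
    w <- leaf_half_width(leaf, s)
    n_t <- max(1L, as.integer(round(2 * w / pitch_mm)) + 1L)
    t_off <- if (n_t == 1L) 0 else seq(-w, w, length.out = n_t)
    phi <- deg2rad(leaf$twist_rate * s)
    local <- cbind(s, t_off * cos(phi), t_off * sin(phi))
    pts[[j]] <- local
  }
  local <- do.call(rbind, pts)
  world <- mm2m(local) %*% t(R)
  sweep(world, 2, leaf$attachment, "+")
}

#' Assemble a chamber scene from a scene spec
#'
#' A scene spec is a plain list describing pots on the chamber floor and the
#' plant in each pot; `build_scene` validates it and instantiates every leaf
#' deterministically from the seed (azimuths spread around the stem with
#' jitter, inclinations and sizes mildly varied). Pot positions are fixed
#' for the lifetime of an experiment, so the same spec + seed always yields
#' a bit-identical scene.
#'
#' @param spec list with elements `pots` (list of `list(id, position =
#'   c(x, y), plant = list(species, n_leaves, leaf_length_mm, leaf_width_mm,
#'   twist_rate, stem_height_m))`), optional `extent` (3 x 2 matrix of box
#'   bounds, m) and `arm_base` (length 3, m). See [scene_spec()].
#' @param seed integer; all scene randomness derives from it
#' @return object of class `chamber_scene`: `pots` (with instantiated
#'   `leaves`, each carrying a scene-global `leaf_id`), `extent`,
#'   `arm_base`, `n_leaves`
#' @export
build_scene <- function(spec, seed) {
  if (missing(seed)) stop("'seed' is required for a reproducible scene")
  if (is.null(spec$pots) || length(spec$pots) < 1)
    stop("scene spec must declare at least one pot")
  extent <- spec$extent
  if (is.null(extent))
    extent <- rbind(x = c(0, 1.5), y = c(0, 1.2), z = c(0, 2))
  arm_base <- if (is.null(spec$arm_base)) c(-0.3, 0.6, 0.4) else spec$arm_base
  pos <- t(vapply(spec$pots, function(p) as.numeric(p$position), numeric(2)))
  if (anyDuplicated(pos)) stop("pot positions must be pairwise distinct")
  inside <- pos[, 1] >= extent[1, 1] & pos[, 1] <= extent[1, 2] &
    pos[, 2] >= extent[2, 1] & pos[, 2] <= extent[2, 2]
  if (!all(inside)) stop("all pot positions must lie inside the chamber footprint")

  with_seed(seed, {
    leaf_id <- 0L
    pots <- vector("list", length(spec$pots))
    for (i in seq_along(spec$pots)) {
      p <- spec$pots[[i]]
      pl <- p$plant
      species <- if (is.null(pl$species)) "flat_round" else pl$species
      n_leaves <- if (is.null(pl$n_leaves)) 3L else as.integer(pl$n_leaves)
      len <- if (is.null(pl$leaf_length_mm))
        (if (species == "flat_round") 70 else 300) else pl$leaf_length_mm
      wid <- if (is.null(pl$leaf_width_mm))
        (if (species == "flat_round") 50 else 40) else pl$leaf_width_mm
      twist <- if (is.null(pl$twist_rate))
        (if (species == "flat_round") 0 else 0.45) else pl$twist_rate
      stem_h <- if (is.null(pl$stem_height_m))
        (if (species == "flat_round") 0.25 else 0.5) else pl$stem_height_m
      pot_h <- 0.15
      base_az <- stats::runif(1, 0, 360)
      leaves <- vector("list", n_leaves)
      for (l in seq_len(n_leaves)) {
        leaf_id <- leaf_id + 1L
        az <- (base_az + (l - 1) * 360 / n_leaves + stats::runif(1, -15, 15)) %% 360
        inc <- stats::runif(1, 15, 35)
        attach_z <- pot_h + stem_h * (0.45 + 0.5 * (l - 1) / max(1L, n_leaves - 1L))
        lf <- leaf_model(species, length_mm = len * stats::runif(1, 0.9, 1.1),
                         width_mm = wid * stats::runif(1, 0.9, 1.1),
                         twist_rate = twist,
                         attachment = c(pos[i, 1], pos[i, 2], min(attach_z, pot_h + stem_h)),
                         azimuth = az, inclination = inc)
        lf$leaf_id <- leaf_id
        leaves[[l]] <- lf
      }
      pots[[i]] <- list(pot_id = if (is.null(p$id)) i else p$id,
                        position = pos[i, ], pot_height = pot_h,
                        stem_height = stem_h, species = species,
                        leaves = leaves)
    }
    structure(list(pots = pots, extent = extent, arm_base = as.numeric(arm_base),
                   n_leaves = leaf_id, seed = as.integer(seed)),
              class = "chamber_scene")
  })
}

#' @export
print.chamber_scene <- function(x, ...) {
  cat(sprintf("<chamber_scene> %d pot(s), %d leaves, extent %.2f x %.2f x %.2f m\n",
              length(x$pots), x$n_leaves,
              diff(x$extent[1, ]), diff(x$extent[2, ]), diff(x$extent[3, ])))
  invisible(x)
}

#' Convenience scene-spec constructor
#'
#' @param n_pots number of pots, laid out on a grid inside the footprint
#' @param species plant style per pot (recycled)
#' @param extent chamber bounding box, 3 x 2 (m)
#' @param arm_base rover arm base position (m)
#' @param plant extra plant fields merged into every pot's plant description
#' @return a scene spec list for [build_scene()]
#' @export
scene_spec <- function(n_pots = 2, species = "flat_round",
                       extent = rbind(x = c(0, 1.5), y = c(0, 1.2), z = c(0, 2)),
                       arm_base = c(-0.3, 0.6, 0.4), plant = list()) {
  species <- rep_len(species, n_pots)
  nx <- ceiling(sqrt(n_pots))
  ny <- ceiling(n_pots / nx)
  xs <- seq(extent[1, 1] + 0.25, extent[1, 2] - 0.25, length.out = max(nx, 2))[seq_len(nx)]
  ys <- seq(extent[2, 1] + 0.25, extent[2, 2] - 0.25, length.out = max(ny, 2))[seq_len(ny)]
  grid <- expand.grid(x = xs, y = ys)[seq_len(n_pots), , drop = FALSE]
  pots <- lapply(seq_len(n_pots), function(i) {
    list(id = i, position = c(grid$x[i], grid$y[i]),
         plant = utils::modifyList(list(species = species[i]), plant))
  })
  list(pots = pots, extent = extent, arm_base = arm_base)
}

#' Sensor presets and custom sensors
#'
#' `tof_coarse` mimics a long-range time-of-flight depth camera: noisy
#' (+/- 1 cm), 0.5-6 m range, 43 x 33 degree field of view. The
#' `profilometer_fine` preset mimics a short-range line-scan laser
#' profilometer with sub-millimeter repeatability (0.2 mm noise; the real
#' device's noise figure is unpublished, 0.2 mm stands in for "highly
#' repeatable").
#'
#' @param kind `"tof_coarse"` or `"profilometer_fine"`
#' @param noise_sd isotropic Gaussian noise, mm
#' @param min_range,max_range working range, m
#' @param fov_h,fov_v field of view, degrees
#' @param sample_pitch surface sample spacing, mm
#' @return object of class `sensor_model`
#' @export
sensor_model <- function(kind = c("tof_coarse", "profilometer_fine"),
                         noise_sd = NULL, min_range = NULL, max_range = NULL,
                         fov_h = NULL, fov_v = NULL, sample_pitch = NULL) {
  kind <- match.arg(kind)
  def <- if (kind == "tof_coarse")
    list(noise_sd = 10, min_range = 0.5, max_range = 6, fov_h = 43, fov_v = 33,
         sample_pitch = 10)
  else
    list(noise_sd = 0.2, min_range = 0.05, max_range = 1.0, fov_h = 60, fov_v = 50,
         sample_pitch = 2)
  s <- list(kind = kind,
            noise_sd = if (is.null(noise_sd)) def$noise_sd else noise_sd,
            min_range = if (is.null(min_range)) def$min_range else min_range,
            max_range = if (is.null(max_range)) def$max_range else max_range,
            fov_h = if (is.null(fov_h)) def$fov_h else fov_h,
            fov_v = if (is.null(fov_v)) def$fov_v else fov_v,
            sample_pitch = if (is.null(sample_pitch)) def$sample_pitch else sample_pitch)
  if (s$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (s$min_range >= s$max_range) stop("'min_range' must be below 'max_range'")
  structure(s, class = "sensor_model")
}

#' Labeled point cloud
#'
#' @param points N x 3 coordinates (m)
#' @param labels integer per-point leaf id; 0 marks non-leaf geometry
#' @param source sensor kind string
#' @return object of class `labeled_cloud`
#' @export
labeled_cloud <- function(points, labels = integer(nrow(points)), source = "unknown") {
  points <- as_points(points)
  labels <- as.integer(labels)
  if (length(labels) != nrow(points))
    stop("'labels' must have one entry per point")
  structure(list(points = points, labels = labels, source = source),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud> %d points (%s), %d leaf labels\n",
              nrow(x$points), x$source, length(setdiff(unique(x$labels), 0L))))
  invisible(x)
}

# All ground-truth surface samples of a scene at a pitch: leaves (labeled),
# stems and pot cylinders (label 0).
scene_surface_samples <- function(scene, pitch_mm) {
  pts <- list(); labs <- list()
  for (pot in scene$pots) {
    for (lf in pot$leaves) {
      p <- leaf_surface_points(lf, pitch_mm)
      pts[[length(pts) + 1L]] <- p
      labs[[length(labs) + 1L]] <- rep(lf$leaf_id, nrow(p))
    }
    # pot + stem as coarse cylinders, non-leaf geometry
    cyl <- function(center_xy, r, z0, z1, pitch) {
      n_th <- max(8L, ceiling(2 * pi * r / mm2m(pitch)))
      zs <- seq(z0, z1, by = max(mm2m(pitch), 0.005))
      th <- seq(0, 2 * pi, length.out = n_th + 1L)[-1]
      g <- expand.grid(th = th, z = zs)
      cbind(center_xy[1] + r * cos(g$th), center_xy[2] + r * sin(g$th), g$z)
    }
    stem_top <- pot$pot_height + pot$stem_height
    p0 <- rbind(cyl(pot$position, 0.10, 0, pot$pot_height, pitch_mm * 2),
                cyl(pot$position, 0.006, pot$pot_height, stem_top, pitch_mm))
    pts[[length(pts) + 1L]] <- p0
    labs[[length(labs) + 1L]] <- rep(0L, nrow(p0))
  }
  list(points = do.call(rbind, pts), labels = unlist(labs))
}

#' Simulate a depth-sensor view of a scene
#'
#' Ground-truth surface samples of every visible object are taken at the
#' sensor's sample pitch, clipped to the sensor frustum (field of view and
#' working range), occlusion-tested with an angular z-buffer (nearest return
#' per angular bin), then perturbed with isotropic Gaussian noise of the
#' sensor's `noise_sd`. With `noise_sd = 0` every returned point lies
#' exactly on its generating surface, and its label identifies the leaf.
#'
#' @param scene a `chamber_scene`
#' @param sensor a `sensor_model`
#' @param viewpoint list with `position` (length 3, m) and `look_at`
#'   (length 3, m)
#' @param seed integer seed for the noise draw
#' @param occlusion logical; disable to keep all in-frustum points
#' @param clip_xy optional 2 x 2 matrix (xlim; ylim) restricting returns to
#'   a ground-plane window (used for per-plant scans)
#' @return a `labeled_cloud` (possibly empty)
#' @export
sample_cloud <- function(scene, sensor, viewpoint, seed, occlusion = TRUE,
                         clip_xy = NULL) {
  stopifnot(inherits(scene, "chamber_scene"), inherits(sensor, "sensor_model"))
  if (missing(seed)) stop("'seed' is required")
  vp <- as.numeric(viewpoint$position)
  look <- as.numeric(viewpoint$look_at)
  surf <- scene_surface_samples(scene, sensor$sample_pitch)
  pts <- surf$points; labs <- surf$labels

  if (!is.null(clip_xy)) {
    keep <- pts[, 1] >= clip_xy[1, 1] & pts[, 1] <= clip_xy[1, 2] &
      pts[, 2] >= clip_xy[2, 1] & pts[, 2] <= clip_xy[2, 2]
    pts <- pts[keep, , drop = FALSE]; labs <- labs[keep]
  }

  # camera frame: z = view direction, x = right, y = down-range vertical
  zc <- unitize(look - vp)
  xr <- c(zc[2] * 1 - zc[3] * 0, zc[3] * 0 - zc[1] * 1, 0)  # cross(zc, +z up)
  xc <- if (vnorm(xr) < 1e-9) c(1, 0, 0) else unitize(xr)
  yc <- c(xc[2] * zc[3] - xc[3] * zc[2],
          xc[3] * zc[1] - xc[1] * zc[3],
          xc[1] * zc[2] - xc[2] * zc[1])  # cross(zc, xc) up to sign
  rel <- sweep(pts, 2, vp)
  pz <- rel %*% zc; px <- rel %*% xc; py <- rel %*% yc
  rng <- sqrt(rowSums(rel^2))
  h_ang <- atan2(px, pz); v_ang <- atan2(py, pz)
  keep <- pz > 0 & rng >= sensor$min_range & rng <= sensor$max_range &
    abs(h_ang) <= deg2rad(sensor$fov_h / 2) &
    abs(v_ang) <= deg2rad(sensor$fov_v / 2)
  pts <- pts[keep, , drop = FALSE]; labs <- labs[keep]
  h_ang <- h_ang[keep]; v_ang <- v_ang[keep]; rng <- rng[keep]
  if (nrow(pts) == 0) return(labeled_cloud(matrix(0, 0, 3), integer(0), sensor$kind))

  if (occlusion) {
    # angular z-buffer at ~1.5x the sample footprint at median range
    bin <- 1.5 * atan2(mm2m(sensor$sample_pitch), stats::median(rng))
    key <- paste(floor(h_ang / bin), floor(v_ang / bin))
    ord <- order(rng)
    first <- ord[!duplicated(key[ord])]
    first <- sort(first)
    pts <- pts[first, , drop = FALSE]; labs <- labs[first]
  }

  if (sensor$noise_sd > 0) {
    pts <- with_seed(seed,
      pts + matrix(stats::rnorm(length(pts), 0, mm2m(sensor$noise_sd)),
                   ncol = 3))
  }
  labeled_cloud(pts, labs, sensor$kind)
}

#' Spectral cube container
#'
#' @param bands strictly increasing band wavelengths, nm
#' @param data H x W x B reflectance array
#' @return object of class `spectral_cube`
#' @export
spectral_cube <- function(bands, data) {
  bands <- as.numeric(bands)
  if (is.unsorted(bands, strictly = TRUE)) stop("'bands' must be strictly increasing")
  if (length(dim(data)) != 3 || dim(data)[3] != length(bands))
    stop("'data' must be H x W x B with B = length(bands)")
  structure(list(bands = bands, data = data), class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d px, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$bands), max(x$bands)))
  invisible(x)
}

#' Render top-view hyperspectral / thermal fixtures for a scene
#'
#' Orthographic top view (z-buffer on the vertical axis) over a ground-plane
#' window, rasterized at `px_mm` per pixel. Every leaf pixel carries that
#' leaf's spectrum and temperature; the background has a distinct flat
#' spectrum and temperature, so region-sampling operations can be verified
#' against the returned ground-truth mask.
#'
#' @param scene a `chamber_scene`
#' @param band_count number of spectral bands (default 56)
#' @param band_range wavelength interval, nm, within 400-900
#' @param leaf_spectra named list: leaf id -> reflectance (scalar, recycled
#'   across bands, or a length-`band_count` vector)
#' @param leaf_temps named list: leaf id -> temperature degC (scalar)
#' @param background list(reflectance, temperature) for non-leaf pixels
#' @param window 2 x 2 matrix (xlim; ylim) of the imaged ground area, m;
#'   default: whole chamber footprint
#' @param px_mm pixel size, mm
#' @return list with `cube` (`spectral_cube`), `thermal` (`thermal_image`),
#'   `mask` (H x W integer leaf ids, 0 = background), `window`, `px_mm`.
#'   Row 1 of every raster is the minimum-y edge of the window.
#' @export
render_fixtures <- function(scene, band_count = 56, band_range = c(400, 900),
                            leaf_spectra = list(), leaf_temps = list(),
                            background = list(reflectance = 0.15, temperature = 22),
                            window = NULL, px_mm = 4) {
  stopifnot(inherits(scene, "chamber_scene"))
  if (band_range[1] < 400 || band_range[2] > 900 || band_range[1] >= band_range[2])
    stop("'band_range' must be an increasing interval within 400-900 nm")
  bands <- seq(band_range[1], band_range[2], length.out = band_count)
  if (is.null(window)) window <- scene$extent[1:2, , drop = FALSE]
  px <- mm2m(px_mm)
  W <- max(1L, ceiling(diff(window[1, ]) / px))
  H <- max(1L, ceiling(diff(window[2, ]) / px))

  spectra <- lapply(leaf_spectra, function(s) {
    s <- as.numeric(s)
    if (length(s) == 1) rep(s, band_count)
    else if (length(s) == band_count) s
    else stop(sprintf("leaf spectrum has length %d, expected %d (band_count)",
                      length(s), band_count))
  })

  mask <- matrix(0L, H, W)
  zbuf <- matrix(-Inf, H, W)
  for (pot in scene$pots) {
    for (lf in pot$leaves) {
      p <- leaf_surface_points(lf, pitch_mm = px_mm / 2)
      ci <- floor((p[, 1] - window[1, 1]) / px) + 1L
      ri <- floor((p[, 2] - window[2, 1]) / px) + 1L
      ok <- ci >= 1L & ci <= W & ri >= 1L & ri <= H
      ci <- ci[ok]; ri <- ri[ok]; z <- p[ok, 3]
      if (!length(ci)) next
      o <- order(z)  # highest z written last wins
      for (j in o) {
        if (z[j] > zbuf[ri[j], ci[j]]) {
          zbuf[ri[j], ci[j]] <- z[j]
          mask[ri[j], ci[j]] <- lf$leaf_id
        }
      }
    }
  }

  cube_data <- array(background$reflectance, dim = c(H, W, band_count))
  thermal <- matrix(background$temperature, H, W)
  ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  for (id in ids) {
    sel <- mask == id
    sp <- spectra[[as.character(id)]]
    if (is.null(sp)) sp <- rep(0.4, band_count)  # default leaf reflectance
    for (b in seq_len(band_count)) {
      plane <- cube_data[, , b]
      plane[sel] <- sp[b]
      cube_data[, , b] <- plane
    }
    tmp <- leaf_temps[[as.character(id)]]
    thermal[sel] <- if (is.null(tmp)) 25 else tmp
  }
  list(cube = spectral_cube(bands, cube_data),
       thermal = structure(thermal, class = c("thermal_image", "matrix")),
       mask = mask, window = window, px_mm = px_mm)
}
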