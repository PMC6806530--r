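# The per-plant acquisition workflow: coarse depth view -> plant height ->
# top-view camera positioning -> fine scan -> segmentation -> probing-site
# selection -> feasibility-gated probe poses and hyperspectral slice scans
# -> measurement sampling on synthetic fixtures -> export. Each stage logs
# an outcome record; a failed stage skips the remaining stages for that
# plant and the run continues.

#' Workflow configuration
#'
#' Gathers every tunable of the acquisition pipeline with the facility's
#' operating constants as defaults: 8 mm probe standoff at 60 degree
#' incidence, 5 mm hyperspectral slices scanned from 0.25 m, a 0.5 m
#' square top-view footprint, a 1.3 m arm reach, and a 56-band 400-900 nm
#' spectral grid.
#'
#' @param coarse_sensor,fine_sensor `sensor_model`s for the two sensing
#'   fidelities
#' @param segmentation `segmentation_params`
#' @param standoff_mm,incidence_deg probe pose constants
#' @param slice_width_mm,scan_distance_m hyperspectral slice scan constants
#' @param footprint_m top-view imaging square side at plant height
#' @param n_sites probing sites requested per plant
#' @param reach_radius_m,probe_clearance_mm workspace constants
#' @param band_count,band_range_nm spectral grid
#' @param red_edge_window_nm red-edge derivative search window
#' @param park_per_plant if TRUE (default) the rover re-parks beside each
#'   pot before probing (arm base 0.5 m from the pot at 0.4 m height); if
#'   FALSE the arm base stays at the scene's `arm_base`, so distant plants
#'   come out unreachable
#' @param seed base seed; per-plant child seeds derive from it
#' @return object of class `workflow_config`
#' @export
workflow_config <- function(coarse_sensor = sensor_model("tof_coarse"),
                            fine_sensor = sensor_model("profilometer_fine"),
                            segmentation = segmentation_params(),
                            standoff_mm = 8, incidence_deg = 60,
                            slice_width_mm = 5, scan_distance_m = 0.25,
                            footprint_m = 0.5, n_sites = 4L,
                            reach_radius_m = 1.3, probe_clearance_mm = 15,
                            band_count = 56, band_range_nm = c(400, 900),
                            red_edge_window_nm = c(690, 730),
                            park_per_plant = TRUE, seed = 1L) {
  cfg <- list(coarse_sensor = coarse_sensor, fine_sensor = fine_sensor,
              segmentation = segmentation, standoff_mm = standoff_mm,
              incidence_deg = incidence_deg, slice_width_mm = slice_width_mm,
              scan_distance_m = scan_distance_m, footprint_m = footprint_m,
              n_sites = as.integer(n_sites), reach_radius_m = reach_radius_m,
              probe_clearance_mm = probe_clearance_mm,
              band_count = as.integer(band_count),
              band_range_nm = band_range_nm,
              red_edge_window_nm = red_edge_window_nm,
              park_per_plant = isTRUE(park_per_plant), seed = as.integer(seed))
  if (cfg$standoff_mm <= 0 || cfg$incidence_deg <= 0 || cfg$incidence_deg > 90 ||
      cfg$slice_width_mm <= 0 || cfg$scan_distance_m <= 0 ||
      cfg$footprint_m <= 0 || cfg$reach_radius_m <= 0)
    stop("workflow parameters out of range")
  structure(cfg, class = "workflow_config")
}

#' Save / load a workflow configuration as JSON
#'
#' @param config `workflow_config`
#' @param path JSON file
#' @return `path` / `workflow_config`
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "workflow_config"))
  plain <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coarse_sensor <- do.call(sensor_model, as.list(x$coarse_sensor))
  x$fine_sensor <- do.call(sensor_model, as.list(x$fine_sensor))
  x$segmentation <- do.call(segmentation_params, as.list(x$segmentation))
  do.call(workflow_config, x)
}

#' Run the full per-plant acquisition workflow on a scene
#'
#' Executes, for every pot in the scene, the rover's acquisition sequence
#' and collects all intermediate products plus a machine-readable stage
#' log. Plant height is estimated as the 99th percentile of the coarse
#' cloud's z within the plant's footprint (robust to noise spikes).
#' Measurements are sampled from fixtures rendered for the scene: YII
#' readings are synthesized per probing site from each leaf's assigned
#' quantum yield, and spectra/temperatures are sampled at the site's pixel.
#'
#' @param scene `chamber_scene`
#' @param config `workflow_config`
#' @param out_dir optional directory for CSV/JSON exports (created); NULL
#'   skips file export
#' @param leaf_yii named list leaf id -> true YII used to synthesize
#'   fluorometer pairs (default 0.75 for every leaf)
#' @return object of class `acquisition_bundle`: per-plant results
#'   (`plants`), the stage `log` (data.frame: plant, stage, status,
#'   reason), `fixtures`, and `exports` (paths)
#' @export
run_acquisition <- function(scene, config = workflow_config(), out_dir = NULL,
                            leaf_yii = list()) {
  stopifnot(inherits(scene, "chamber_scene"), inherits(config, "workflow_config"))
  log_rows <- list()
  note <- function(plant, stage, status, reason = "") {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      plant = plant, stage = stage, status = status, reason = reason,
      stringsAsFactors = FALSE)
  }

  # fixtures once per scene
  yii_map <- leaf_yii
  spectra <- list(); temps <- list()
  for (pot in scene$pots) for (lf in pot$leaves) {
    id <- as.character(lf$leaf_id)
    if (is.null(yii_map[[id]])) yii_map[[id]] <- 0.75
    # a crude green-leaf spectrum: low red, red-edge rise, high NIR
    bands <- seq(config$band_range_nm[1], config$band_range_nm[2],
                 length.out = config$band_count)
    spectra[[id]] <- 0.08 + 0.42 / (1 + exp(-(bands - 710) / 8))
    temps[[id]] <- 24 + 0.5 * lf$leaf_id
  }
  fixtures <- render_fixtures(scene, band_count = config$band_count,
                              band_range = config$band_range_nm,
                              leaf_spectra = spectra, leaf_temps = temps)

  plants <- vector("list", length(scene$pots))
  names(plants) <- vapply(scene$pots, function(p) as.character(p$pot_id), character(1))
  for (pi in seq_along(scene$pots)) {
    pot <- scene$pots[[pi]]
    pid <- as.character(pot$pot_id)
    seed_i <- child_seed(config$seed, pi)
    arm_base <- if (config$park_per_plant)
      c(pot$position[1], pot$position[2] - 0.5, 0.4) else scene$arm_base
    ws <- workspace_model(arm_base, config$reach_radius_m,
                          config$probe_clearance_mm)
    res <- list(pot_id = pot$pot_id, arm_base = arm_base)
    half <- config$footprint_m / 2
    clip <- rbind(pot$position[1] + c(-half, half),
                  pot$position[2] + c(-half, half))

    # stage 1: coarse depth view and plant height
    coarse_vp <- list(position = c(pot$position, scene$extent[3, 2]),
                      look_at = c(pot$position, 0))
    coarse <- sample_cloud(scene, config$coarse_sensor, coarse_vp,
                           seed = seed_i, clip_xy = clip)
    if (nrow(coarse$points) == 0) {
      note(pid, "coarse_cloud", "failed", "empty_view")
      plants[[pi]] <- res
      next
    }
    height <- stats::quantile(coarse$points[, 3], 0.99, names = FALSE)
    res$plant_height <- height
    note(pid, "coarse_cloud", "ok")

    # stage 2: top-view camera placement for the imaging footprint
    top <- plan_topview_pose(height, c(config$coarse_sensor$fov_h,
                                       config$coarse_sensor$fov_v),
                             config$footprint_m, pot$position)
    res$topview <- top
    note(pid, "topview_pose", "ok")

    # stage 3: fine sweep from the profilometer's short working distance
    # above the plant (the top-view pose is for the imaging cameras; the
    # profilometer works much closer)
    fine_z <- height + 0.35 * (config$fine_sensor$min_range +
                                 config$fine_sensor$max_range)
    fine <- sample_cloud(scene, config$fine_sensor,
                         list(position = c(pot$position, fine_z),
                              look_at = c(pot$position, height)),
                         seed = child_seed(seed_i, 2), clip_xy = clip)
    if (nrow(fine$points) < config$segmentation$min_size) {
      note(pid, "fine_cloud", "failed", "too_few_points")
      plants[[pi]] <- res
      next
    }
    res$fine_cloud <- fine
    note(pid, "fine_cloud", "ok")

    # stage 4: normals + segmentation
    field <- estimate_normals_curvature(fine, k = config$segmentation$k,
                                        view_origin = top$camera)
    seg <- region_grow(fine, field, config$segmentation)
    res$segmentation <- seg
    if (!length(seg$segments)) {
      note(pid, "segmentation", "failed", "no_segments")
      plants[[pi]] <- res
      next
    }
    note(pid, "segmentation", "ok")

    # stage 5: probing sites
    sites <- select_probe_sites(seg, fine, field, config$n_sites)
    res$sites <- sites
    if (!nrow(sites)) {
      note(pid, "sites", "failed", "no_sites")
      plants[[pi]] <- res
      next
    }
    note(pid, "sites", "ok")

    # stage 6: probe poses with feasibility gating
    poses <- vector("list", nrow(sites))
    verdicts <- character(nrow(sites))
    for (si in seq_len(nrow(sites))) {
      nrm <- unitize(c(sites$nx[si], sites$ny[si], sites$nz[si]))
      seg_idx <- seg$segments[[sites$segment[si]]]
      hint <- principal_axes(fine$points[seg_idx, , drop = FALSE])$axes[, 1]
      pose <- compute_probe_pose(c(sites$x[si], sites$y[si], sites$z[si]),
                                 nrm, config$standoff_mm, config$incidence_deg,
                                 azimuth_hint = hint)
      verdict <- check_feasible(pose, fine, ws, exclude = seg_idx)
      poses[[si]] <- pose
      verdicts[si] <- verdict$reason
      note(pid, sprintf("probe_pose_site%d", si),
           if (verdict$feasible) "ok" else "skipped", verdict$reason)
    }
    res$probe_poses <- poses
    res$feasibility <- verdicts

    # stage 7: hyperspectral slice plans for each segment
    res$slice_plans <- lapply(seq_along(seg$segments), function(si) {
      idx <- seg$segments[[si]]
      pl <- slice_leaf(fine$points[idx, , drop = FALSE], config$slice_width_mm)
      sub_field <- structure(list(
        normals = field$normals[idx, , drop = FALSE],
        curvatures = field$curvatures[idx], valid = field$valid[idx],
        k = field$k), class = "normal_field")
      plan_line_scan_poses(pl, field = sub_field,
                           working_distance = config$scan_distance_m)
    })
    note(pid, "slice_plans", "ok")

    # stage 8: measurements at feasible sites
    readings <- list()
    for (si in seq_len(nrow(sites))) {
      if (verdicts[si] != "ok") next
      leaf_id <- fine$labels[sites$index[si]]
      if (leaf_id == 0L) {
        note(pid, sprintf("measure_site%d", si), "skipped", "non_leaf_site")
        next
      }
      yii_true <- yii_map[[as.character(leaf_id)]]
      FMp <- 1
      Fm <- with_seed(child_seed(seed_i, 100 + si),
                      min(FMp, max(0, (1 - yii_true) * FMp + stats::rnorm(1, 0, 0.01))))
      yii <- compute_yii(Fm, FMp)
      px <- floor((sites$x[si] - fixtures$window[1, 1]) / mm2m(fixtures$px_mm)) + 1L
      py <- floor((sites$y[si] - fixtures$window[2, 1]) / mm2m(fixtures$px_mm)) + 1L
      d <- dim(fixtures$cube$data)
      spec <- temp <- NULL
      if (px >= 1 && px <= d[2] && py >= 1 && py <= d[1]) {
        shape <- region_circle(px, py, 2.5)
        spec <- tryCatch(sample_region_spectrum(fixtures$cube, shape),
                         error = function(e) NULL)
        temp <- tryCatch(sample_region_temperature(fixtures$thermal, shape),
                         error = function(e) NULL)
      }
      red_edge <- if (!is.null(spec))
        red_edge_derivative(spec$spectrum, spec$bands, config$red_edge_window_nm)
      else NULL
      readings[[length(readings) + 1L]] <- list(
        site_index = si, x = sites$x[si], y = sites$y[si], z = sites$z[si],
        leaf_id = leaf_id, YII = yii, spectrum = spec, red_edge = red_edge,
        temperature = temp)
      note(pid, sprintf("measure_site%d", si), "ok")
    }
    res$readings <- readings
    plants[[pi]] <- res
  }

  log <- do.call(rbind, log_rows)
  exports <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yii_rows <- list()
    for (pid in names(plants)) {
      for (r in plants[[pid]]$readings) {
        yii_rows[[length(yii_rows) + 1L]] <- data.frame(
          plant = pid, site_index = r$site_index, x = r$x, y = r$y, z = r$z,
          YII = r$YII, stringsAsFactors = FALSE)
      }
    }
    if (length(yii_rows)) {
      df <- do.call(rbind, yii_rows)
      p1 <- file.path(out_dir, "yii_readings.csv")
      p2 <- file.path(out_dir, "yii_readings.json")
      export_records(df, p1, "csv")
      export_records(df, p2, "json")
      exports <- c(exports, p1, p2)
    }
    p3 <- file.path(out_dir, "stage_log.csv")
    utils::write.csv(log, p3, row.names = FALSE)
    exports <- c(exports, p3)
  }
  structure(list(plants = plants, log = log, fixtures = fixtures,
                 exports = exports, config = config),
            class = "acquisition_bundle")
}

#' @export
print.acquisition_bundle <- function(x, ...) {
  ok <- sum(x$log$status == "ok")
  cat(sprintf("<acquisition_bundle> %d plant(s); %d/%d stages ok\n",
              length(x$plants), ok, nrow(x$log)))
  invisible(x)
}
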