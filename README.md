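# phenorover

**phenorover** is a desk-scale R implementation of the computational
pipeline behind a *sensor-to-plant* phenotyping facility: an array of
controlled-environment growth chambers visited by a robotic rover that
carries its sensors to the plants, maps each chamber in 3D, finds smooth
leaf regions, and places a fluorometer probe and a hyperspectral line-scan
camera on leaf surfaces. Everything runs on synthetic data that the package
generates itself, so the full chain — scene, point clouds, segmentation,
pose planning, sensor measurements, chamber control, experimental design —
is reproducible and testable on a laptop with no downloads.

It is intended for plant-phenotyping and agricultural-robotics researchers
who want to prototype or teach the algorithms of such a facility:
point-cloud leaf segmentation, probing-pose geometry, PAM-fluorometry and
hyperspectral measurement math, chamber control logic, and split-plot
experimental design.

## What it computes

* **Two-fidelity sensing.** A coarse time-of-flight view (±1 cm noise,
  0.5–6 m range, 43°×33° FOV) locates plants and estimates height; a fine
  laser-profilometer sweep (0.2 mm) supports geometry. `sample_cloud()`
  simulates both, with frustum clipping, z-buffer occlusion, and calibrated
  Gaussian noise, over parametric plants built by `build_scene()`.
* **Surface normals and curvature.** For each point, PCA of its
  k-neighborhood: the normal is the smallest-eigenvalue eigenvector and the
  curvature is the surface variation λ_min/(λ₁+λ₂+λ₃) ∈ [0, 1/3]
  (`estimate_normals_curvature()`, exact `knn()`).
* **Leaf segmentation.** Region growing with a smoothness constraint
  (`region_grow()`): seeds in order of increasing curvature; a neighbor
  joins a region when its normal is within θ_smooth of the region seed's
  normal, and propagates growth only when its curvature ≤ c_max; small
  regions are rejected as noise. A flat round (soybean-like) leaflet comes
  out as one segment; an elongated twisted (maize-like) leaf splits into
  several probing regions under a tight θ.
* **Probe and scan planning.** Sites are the largest inscribed flat
  neighborhoods of each segment (`select_probe_sites()`); the probe axis is
  placed 8 mm from the leaf at a 60° angle to the surface
  (`compute_probe_pose()`), checked against a 1.3 m arm reach and a swept
  clearance cylinder (`check_feasible()`). Leaf segments are dissected into
  5 mm slices along their major axis (`slice_leaf()`) and imaged from
  0.25 m as parallel to the slice as possible (`plan_line_scan_poses()`);
  top-view cameras cover a 0.5 × 0.5 m footprint (`plan_topview_pose()`).
* **Measurements.** Effective PSII quantum yield
  YII = (F′M − F)/F′M (`compute_yii()`); white/dark reflectance calibration
  R = (raw − dark)/(white − dark); mean spectra and temperatures over drawn
  circles/lines on 56-band synthetic images; red-edge first derivative
  around 700–720 nm (`red_edge_derivative()`); CSV/JSON/PNG export.
* **Chamber simulation.** `chamber_step()`/`run_schedule()` reproduce the
  controller logic: PI temperature tracking in 10–44 °C, dual-actuation CO₂
  (solenoid release below setpoint, scrub fan above, 150–5000 PPM, never
  both), additive-only drip irrigation on %VWC, the 7-channel LED mix,
  photoperiod offsets per chamber, and the curtain/damper imaging
  interlock.
* **Experimental design.** Chambers are whole plots, pots split plots:
  `enumerate_combinations()` (2×2×2 = 8 environments),
  `assign_splitplot()` (8 × 14 = 112 plants per run), `new_replication()`,
  and `fit_response_surface()` — a per-genotype quadratic over temperatures
  {22, 24, 26, 28} °C whose optimum is the vertex −b/(2c), clipped to the
  design range.

## Worked example

```r
library(phenorover)

scene  <- build_scene(scene_spec(2, c("flat_round", "elongated_twisted")), seed = 11)
bundle <- run_acquisition(scene, workflow_config(seed = 4), out_dir = "demo_out")
bundle
#> <acquisition_bundle> 2 plant(s); 26/27 stages ok

p1 <- bundle$plants[[1]]
p1$segmentation
#> <leaf_segmentation> 3 segment(s) over 2879 points, 1184 noise
#>   sizes: 742, 558, 395
sprintf("plant height: %.3f m", p1$plant_height)
#> [1] "plant height: 0.413 m"

r <- p1$readings[[1]]
sprintf("site %d YII = %.3f, leaf temp = %.1f C, red edge = %.1f nm",
        r$site_index, r$YII, r$temperature$mean_temp, r$red_edge$wavelength)
#> [1] "site 1 YII = 0.756, leaf temp = 25.5 C, red edge = 709.1 nm"
```

The two plants are processed through the full per-plant sequence (coarse
height estimate, top-view pose, fine sweep, segmentation, site selection,
feasibility-gated probe poses, slice-scan plans, fixture measurements); 26
of 27 stages succeed and one probe pose is skipped with the
machine-readable reason `collision`. The soybean-style plant's three flat
leaflets each come out as one segment; sites are ranked by their inscribed
flat radius (`score`, in meters). The YII values scatter around the leaf's
true quantum yield of 0.75 through the synthesized fluorescence pairs, the
leaf temperature is read off the thermal fixture, and the red-edge
wavelength lands on the 709 nm band of the 56-band grid — the band nearest
the fixture spectrum's 710 nm inflection. `demo_out/` then contains
`yii_readings.csv` (columns `plant, site_index, x, y, z, YII`), the JSON
equivalent, and the per-stage log.

A command-line surface wraps the same pipeline:

```sh
Rscript inst/cli/phenorover.R simulate-scene --pots 2 --out scene.json --seed 7
Rscript inst/cli/phenorover.R sample-cloud   --scene scene.json --out cloud.ply --seed 7
Rscript inst/cli/phenorover.R segment        --in cloud.ply --theta 10 --cmax 0.05 --min-size 100 --out seg.json
Rscript inst/cli/phenorover.R plan           --cloud cloud.ply --seg seg.json --sites 4 --out plan.json
```

## Documentation

The methods vignette (`vignettes/phenorover-methods.Rmd`) describes the
models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical design choices.
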