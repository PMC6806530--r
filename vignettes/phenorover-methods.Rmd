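---
title: "phenorover: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenorover: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorover)
```

# The system being modeled

phenorover reproduces, at desk scale, the computational pipeline of a
sensor-to-plant phenotyping facility: growth chambers that each hold a few
potted plants under independently controlled temperature, humidity, CO2,
irrigation and LED lighting, and a rover whose arm-mounted sensing head
builds a 3D map of each chamber, segments leaves, and places measurement
probes on leaf surfaces. The package implements the algorithms, not the
hardware: every input is produced by the synthetic scene generator, so the
whole chain is deterministic, seedable and testable offline.

# Synthetic scenes and sensing

## Leaf surfaces

Two parametric leaf styles span the geometric contrast that matters for
segmentation:

* `flat_round` — an elliptical planar disk (minor-species leaflet, e.g.
  soybean). Length and width default to 70 x 50 mm.
* `elongated_twisted` — a ruled ribbon whose elliptical cross-section
  rotates about the major axis at `twist_rate` degrees per millimeter
  (maize-like). Defaults: 300 x 40 mm, 0.45 deg/mm, i.e. ~135 degrees of
  twist end to end, a realistic mid-season maize value.

These are deliberately minimal: they reproduce "flat leaves come out
whole, twisted leaves split into several probing regions" without
simulating veins, serration, droop or growth. Plants are 3 leaves on a
vertical stem in a 0.1 m pot; azimuths are spread around the stem with
jitter, inclinations drawn from 15-35 degrees.

## Sensors

`sensor_model()` ships two presets. `tof_coarse` reflects a long-range
time-of-flight depth camera: 10 mm isotropic Gaussian noise (the "rough
+/- 1 cm map"), 0.5-6 m range, 43 x 33 degree field of view, 10 mm sample
pitch. `profilometer_fine` stands in for a short-range line-scan laser
profilometer; its repeatability is not published, so the preset uses
0.2 mm noise ("highly repeatable") with a 0.05-1 m working range and 2 mm
pitch — both documented, both overridable.

`sample_cloud()` samples every surface at the sensor's pitch, clips to the
frustum and range, resolves occlusion with an angular z-buffer (nearest
return per angular bin of ~1.5 sample footprints — no multi-return or
mixed-pixel modeling), and then adds noise. With zero noise every returned
point lies exactly on its generating surface and carries the true leaf id,
which is what makes label-based quality scoring possible.

## Fixtures

`render_fixtures()` rasterizes an orthographic top view into a
hyperspectral cube (default 56 bands uniformly spanning 400-900 nm; the
real instrument's exact band centers are unpublished, only the count and
the VNIR range), a thermal image, and a ground-truth leaf mask. Leaf
pixels carry exactly their assigned spectrum/temperature, so region
sampling can be checked against pixel-counting oracles.

# Geometry

Normals and curvature come from PCA of the k-nearest neighborhood: the
normal is the eigenvector of the smallest covariance eigenvalue, oriented
toward the sensor; the curvature is the surface variation
lambda_min / (lambda_1 + lambda_2 + lambda_3), bounded by 1/3. The
facility's neighborhood size is unreported; the default is k = 10, which
at the fine 2 mm pitch gives a ~4 mm support — small enough to track a
twisting blade, large enough to average sensor noise. Coarse clouds
(10 mm pitch) warrant a larger k of ~30; both are plain arguments. Eigen ties
break by eigenvalue order, and eigenvector signs are fixed by making the
first nonzero component positive, so all geometry is deterministic.

# Segmentation: region growing with a smoothness constraint

Seeds are processed in order of increasing curvature (ties by index). A
neighbor joins a region when the angle between its normal and the **normal
of the region's seed** is at most `theta_smooth`; a joined point continues
the growth only if its own curvature is at most `c_max`; finished regions
below `min_size` points go to noise, as do points with degenerate normals.

The seed-normal comparison is a deliberate design choice. Comparing each
neighbor with the *local* point's normal instead (the other common variant)
makes the accepted angle accumulate: on a smoothly twisted ribbon sampled
at 3 mm pitch, adjacent normals differ by ~1.35 degrees, so any usable
threshold chains through the entire twist and a maize-like leaf can never
split, noiselessly, into multiple probing regions. Anchoring the test at
the region's seed bounds the total normal span of a segment by roughly
2 x theta_smooth, which is exactly the "segment size is tunable" behavior
the system needs: theta = 60 degrees leaves the default ribbon in 2
pieces, theta = 10 in about 8. Flat surfaces are unaffected (all normals
equal the seed's).

Defaults `theta_smooth = 10` degrees, `c_max = 0.05`, `min_size = 100` are
calibrated to the package's fixtures, not to any hardware: they keep a
flat leaflet whole at the fine pitch while splitting the default twisted
ribbon, and 100 points at 2 mm pitch is ~4 cm^2 of leaf — a sensible
minimum area to aim a probe at.

# Probing and scan planning

* **Site score.** A probing site should sit in the middle of a large flat
  patch. The score is the largest radius r such that the points within r
  of the site (a) fit a plane with RMS residual <= 1 mm and (b) fill the
  r-disk (at least 60% of the count expected from the segment's median
  sampling density). The coverage clause makes the score the *inscribed*
  flat radius: without it, every point of a perfectly flat segment —
  including its rim — would score the segment diameter. The density unit
  is segment-global because rim points locally look sparse and would
  otherwise grade themselves on a curve. Radii are searched on a geometric
  grid (ratio 0.75), candidates capped at 250 per segment by uniform index
  subsampling.
* **Probe pose.** Tip at `site - standoff * axis` with
  `axis = sin(incidence) * normal + cos(incidence) * t_hat`; defaults 8 mm
  and 60 degrees, the hand-held leaf-clip geometry the robot mimics. The
  tilt azimuth t_hat is the tangent-plane projection of the site's segment
  major axis, keeping the probe body over the leaf; at 90 degrees the axis
  is the normal and the azimuth is irrelevant.
* **Feasibility.** Unreachable if the tip is farther than the 1.3 m reach
  radius from the arm base; collision if any non-target point enters the
  15 mm clearance cylinder swept from tip to target. This is a
  straight-approach check — full arm path planning is out of scope. In the
  acquisition workflow the rover re-parks 0.5 m beside each pot by default
  (`park_per_plant`), mirroring how the real vehicle drives to each plant;
  disabling it exercises the unreachable branch.
* **Slices.** Points are binned by projection on the segment's major axis
  into ceiling(extent / 5 mm) half-open bins starting at the minimum
  projection; the last bin may be narrower, empty bins are kept so slice
  index maps to position. Per-slice cameras sit exactly 0.25 m along the
  mean slice normal, scan direction = major axis projected into the image
  plane. Slices with fewer than 3 points inherit the nearest planned pose.
* **Top view.** Standoff = footprint / (2 tan(fov_min / 2)) above the
  plant, using the narrower FOV axis so the full 0.5 m square is covered.

# Measurements

YII = (F'M - F) / F'M, with F > F'M flagged by a warning but returned
(negative) rather than censored. Calibration is the per-band linear map
(raw - dark) / (white - dark); a band with white <= dark is a hard error
naming the band. Region sampling uses pixel-center membership — no
antialiasing, so results are integers of pixels and exactly reproducible.
The red-edge derivative uses central differences on the band grid
(one-sided at the edges), searched in a 690-730 nm window (bracketing the
700-720 nm chlorophyll-sensitive rise, and wide enough to hold >= 3 of the
default bands); flat-spectrum ties resolve to the lowest wavelength.

# Chamber simulation

The aim is the controller's *actuator logic and envelopes*, not chamber
thermodynamics. Per 1-minute step:

* Temperature: PI command (Kp = 0.4, Ki = 0.02 per minute) with
  conditional-integration anti-windup, rate-limited to 1.5 degC/min, state
  clamped to the 10-44 degC envelope (+/- 0.5 safety margin). Gains are
  tuned for overshoot-free tracking to well under 0.1 degC at steady
  state; the real PID gains are unpublished.
* CO2: bang-bang with a +/- 25 PPM deadband — solenoid adds (25 PPM/min,
  throttled so it never crosses the setpoint) below, scrub fan removes
  (10 PPM/min) above, never both in one step. Addition deliberately
  outpaces removal, matching the described asymmetry. Setpoints outside
  150-5000 PPM are rejected at construction.
* Irrigation: drip valve open iff VWC < setpoint; the controller's water
  flux is >= 0 at every step of every trace (additive-only) —
  evapotranspiration is a disturbance, not an actuator.
* RH: rate-limited tracking within bounds only; humidification physics is
  out of scope. LEDs are commanded channel fractions of the 7-color
  module mix (22/22/14/6/12/16/9 percent); no radiometric model.
* Scheduling: per-chamber event lists on a 24 h virtual clock shifted by
  the chamber's photoperiod offset, so a rover can meet every chamber at
  the same virtual time of day; conflicting same-time patches are
  rejected. The trace logs setpoints, process values and actuator states
  every step, like the real controller's per-minute log.

Disturbances default to zero; `default_disturbances()` gives a mildly
loaded chamber (2 PPM/min CO2 draw-down, 0.02 %VWC/min evapotranspiration,
thermal leakage toward 20 degC).

# Experimental design

Chambers are whole-plot units, pots split-plot units. Randomization is by
uniform seeded permutations: combinations are replicated equally when
there are fewer than 8 (e.g. 2 temperature levels -> 4 chambers each), and
genotypes are independently permuted per chamber. More combinations than
chambers is an error directing the user to blocked multi-run designs.
`new_replication()` derives the next run's seed from (seed, run id), so
rerunning with the original seed reproducibly yields a *different* layout
for run 2 — the documented stream-splitting contract.

The response-surface fit is an ordinary least-squares quadratic per
genotype. The optimum is the vertex -b/(2c) when the fit is concave and
the vertex is inside the design range; otherwise the range endpoint with
the higher fitted value — the quadratic is a local approximation and
extrapolating its vertex outside the tested 22-28 degC range is not
defensible. Genotypes with fewer than 3 distinct levels are flagged, not
fitted. The repeated-measures mixed-model analysis of split-plot data is
intentionally out of scope.

# What a green test does and does not establish

The synthetic generator emulates: two sensing fidelities with calibrated
noise, occlusion, labeled surfaces, leaf-style geometric contrast, and
fixtures with exact ground truth. It does not emulate: leaf droop or
growth, veins and specular reflectance, multi-return depth artifacts, wind
motion, radiometric LED-leaf interaction, or real fluorescence kinetics
(YII readings are synthesized from an assigned per-leaf yield plus 1%
noise). Passing tests therefore establish the *algorithms* — geometry,
segmentation logic, pose math, control logic, design arithmetic — under a
stated world, not instrument-level performance on real plants.

# Numerical conventions

Meters internally, millimeters at configuration boundaries; right-handed
z-up frame with the chamber floor at z = 0. All RNG flows through
`with_seed()` so library calls never disturb the caller's RNG stream;
child seeds derive as (seed * 1103 + index * 12289) mod (2^31 - 19),
keeping every derived seed a valid 32-bit integer. Ties: knn by point
index, seed order by (curvature, index), eigen sign by first nonzero
component, flat-spectrum red edge by lowest wavelength, slice bins
half-open with the maximum clamped into the last bin.

# Known limitations

* The z-buffer visibility model decimates ~50% of surface samples at
  oblique viewing and can drop thin structures at long range.
* Site scoring assumes roughly uniform sampling density inside a segment;
  strongly nonuniform clouds (e.g. merged multi-view scans) would need a
  density-aware coverage test.
* The chamber model has no cross-coupling (e.g. temperature does not
  change RH); envelopes and interlocks are faithful, physics is not.
* PLY/PCD I/O is ASCII-only by design (inspectable fixtures); binary
  variants are not parsed.
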