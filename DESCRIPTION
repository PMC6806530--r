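Package: phenorover
Title: Sensor-to-Plant Phenotyping Toolkit: Point Clouds, Leaf Probing,
    Chamber Control and Split-Plot Design
Version: 0.1.0
Authors@R: person("phenorover", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale re-creation of the computational pipeline of a
    robotic plant-phenotyping facility in which a sensor-laden rover visits
    growth chambers and places probes on leaves. Provides synthetic chamber
    scene and labeled point-cloud generation at two sensor fidelities,
    PCA-based surface normal and curvature estimation, leaf segmentation by
    3D region growing with a smoothness constraint, probing-site selection
    and probe/camera pose planning under standoff and incidence constraints,
    hyperspectral line-scan slice planning, sensor measurement math (PSII
    effective quantum yield, reflectance calibration, red-edge derivative,
    region-shape spectral and thermal sampling), a discrete-time growth
    chamber control-loop simulator, and split-plot randomization with
    quadratic response-surface fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
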