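Package: micromag
Title: Stray Fields, Magnetophoresis Kinetics and Occupancy Statistics
    for Micro-Magnet Cell Guidance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the guidance of magnetically labeled cells onto
    micropatterned thin-film magnets. Provides closed-form stray-field and
    attraction-force maps of uniformly magnetized rectangular micro-magnets
    (equivalent surface-charge model), hot-spot detection and force-anisotropy
    metrics, overdamped drag-balance magnetophoresis (terminal velocities,
    speed-ratio predictions, trajectory integration), pattern-geometry tools
    (rasterization, disk dilation, effective-area fractions for a
    uniform-landing null), occupancy statistics with one-sample proportion and
    Welch t tests, and a seeded synthetic-data generator for labeled cell
    populations, uniform landings, and noisy constant-velocity tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    ggplot2
Config/testthat/edition: 3
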