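Package: plethyclust
Title: Breath Detection and Waveform Cluster Analysis for Whole Body Plethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Segments continuous whole body plethysmography (WBP) airflow
    recordings into individual breaths by threshold crossing with
    zero-crossing onset refinement, bins breaths into duration domains,
    clusters waveform shapes by principal component analysis and Ward
    hierarchical linkage with an elbow-based choice of cluster count, and
    uses cluster membership to annotate respiratory behavior (sniffing,
    common and uncommon tidal breathing, augmented breaths), track cluster
    prevalence across experimental periods, and compute classical
    ventilation metrics (respiratory rate, tidal volume, minute
    ventilation). Includes a seeded synthetic-trace generator with ground
    truth for end-to-end validation, model persistence for classifying new
    recordings against established clusters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
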