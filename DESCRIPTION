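Package: pecktrack
Title: Peck-Tracking Analysis of Touchscreen Categorization Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing per-peck touchscreen logs from two-class
    visual categorization experiments with birds. Provides a validated CSV
    peck-log data model, spatial 15x15 heatmap statistics with difference
    maps and cumulative peck distributions, a Kolmogorov-Smirnov comparison
    of correct- versus error-trial peck concentration, k-nearest-neighbour
    decoding of stimulus class from peck coordinates in correct-correct,
    correct-error and error-error modes with a shuffled-label null and
    paired-t significance, choice-performance summaries with effect sizes,
    pixelwise-correlation stimulus selection with a size/black-area
    confound check, and a synthetic session generator parameterized as
    interpretable pecking-strategy archetypes so the full pipeline can be
    exercised and validated without raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
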