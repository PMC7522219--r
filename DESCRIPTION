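Package: lrcpart
Title: Light-Response Curve Fitting and PSII Electron-Flow Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the nonasymptotic (Ye) and non-rectangular hyperbola (NH)
    light-response models to leaf-level curves of net photosynthesis (An-I)
    and PSII electron transport (J-I), partitions total electron flow into
    RuBP-carboxylation (JC) and RuBP-oxygenation (JO) streams from combined
    gas-exchange and chlorophyll-fluorescence measurements, and returns the
    closed-form derived quantities of each curve (maximum, saturation
    irradiance, light compensation point) with replicate statistics and a
    Table-style model-versus-observation intercomparison. Includes a
    synthetic-data generator emulating descending-light-step protocols and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
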