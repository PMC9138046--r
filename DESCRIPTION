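Package: abandonCarbon
Title: Carbon-Cycle Impact of Cropland Abandonment via Calibrated Land-Use
    Scenarios and a Reduced Dynamic Vegetation Model
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the terrestrial carbon sink created by
    large-scale cropland abandonment. National cropland statistics are
    reconciled across sources (arable-land records anchored to sown-area
    dynamics), converted to an annual adjustment rate, and used to rescale a
    gridded cropland-fraction field without altering its spatial pattern. The
    calibrated land-use forcing drives a reduced-complexity dynamic vegetation
    model (five plant functional types; leaf, fine-root, coarse-root, sapwood
    and heartwood vegetation pools; metabolic and structural litter; a
    decomposer pool; fast, intermediate and slow soil pools) with Jarvis-type
    co-limited photosynthesis, first-order turnover and a temperature- and
    moisture-dependent decomposition cascade. Three land-use scenarios (fixed,
    default, optimized cropland) are run from a common spin-up and differenced
    to attribute the abandonment-driven sink and its vegetation/soil split.
    Includes a synthetic-data module generating country tables, gridded
    cropland and climate forcing with the statistical structure of the real
    sources, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'synthetic.R'
    'calibration.R'
    'dgvm-flux.R'
    'dgvm-landuse.R'
    'dgvm-step.R'
    'spinup.R'
    'scenario.R'
    'io.R'
    'pipeline.R'
    'abandonCarbon-package.R'
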