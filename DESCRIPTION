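Package: npcrowd
Title: Ratiometric FRET Quantification of Protein Crowding in the
    Nuclear Pore Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying macromolecular crowding from the
    GimRET FRET probe (CFP donor, glycine-inserted YFP acceptor) fused
    to nucleoporins.  Implements band-integrated acceptor/donor ratio
    computation on emission spectra, calibration of the crowding-
    dependent acceptor quench against crowder concentration,
    nuclear-envelope rim segmentation and per-cell ratiometric
    quantification of two-channel interphase images, and time-resolved
    localization/crowding analysis of post-mitotic nuclear pore complex
    reassembly with half-time extraction.  A synthetic-data module
    generates emission spectra, interphase cell phantoms, immunostain
    pairs and anaphase-to-G1 time-lapse stacks with analytic ground
    truth, so every stage of the pipeline can be validated as a
    parameter-recovery experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra.R'
    'calibration.R'
    'presets.R'
    'phantom-spectra.R'
    'phantom-cells.R'
    'phantom-timelapse.R'
    'segment.R'
    'quantify-interphase.R'
    'statistics.R'
    'quantify-mitotic.R'
    'io.R'
    'pipeline.R'
    'npcrowd-package.R'
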