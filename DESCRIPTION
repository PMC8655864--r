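Package: kirstoich
Title: Subunit Stoichiometry Inference for Tetrameric Inward-Rectifier
    Potassium Channels from Oocyte Voltage-Clamp Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces two-electrode voltage-clamp recordings of Xenopus
    oocytes co-expressing wild-type and mutant Kir2.1 subunits to
    barium-sensitive, Kir-specific currents with leak and rectification
    quality control, normalizes them to same-batch wild-type controls,
    and infers how many mutant subunits suffice to disable a tetrameric
    channel by ranking a binomial subunit-assembly model family
    (exactly-n wild-type, at-least-n wild-type, no co-assembly) by
    root-mean-square deviation. Includes a synthetic-data generator
    emulating oocyte-batch expression variability with known ground
    truth, bootstrap model-selection frequencies, and JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
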