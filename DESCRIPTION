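Package: ntk
Title: Indentation Elastography and Voltage-Dye Electrophysiology for
    Engineered Neural Tissue
Version: 1.0.0
Authors@R:
    person("NTK", "Developers", email = "ntk-dev@example.org",
           role = c("aut", "cre"))
Description: Tools for non-destructive characterization of engineered neural
    tissues. Estimates the elastic modulus of very soft hydrogel scaffolds
    from sphere-indentation geometry using a thin-film-corrected Hertz
    contact model, including extraction of gel thickness and indentation
    depth from two-channel confocal z-stacks. Converts voltage-sensitive-dye
    plate-reader fluorescence into membrane-potential changes with
    dye-sensitivity calibration, per-well quality control, and group
    statistics. Ships synthetic-data generators with known ground truth for
    every pipeline stage, plus plain-text readers and writers and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
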