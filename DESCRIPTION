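Package: thiogag
Title: Modelling of S-Linked Heparosan Analogs: Masses, Cleavage Rules,
    Ring Puckering and Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("thiogag", "maintainers", email = "thiogag@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling thio-glycosidic (S-linked) analogs of
    heparosan and heparan sulfate. Represents modified glycosaminoglycan
    chains, predicts elemental compositions and negative-mode ion masses,
    and simulates heparanase/heparin-lyase cleavage-site rules. Computes
    Cremer-Pople puckering coordinates of pyranose rings, classifies them
    among the 38 canonical six-membered-ring conformers, and exports
    sinusoidal equal-area projections. Includes a desk-scale conformational
    ensemble generator that Boltzmann-samples glycosidic bond geometry from
    harmonic force-field parameters, plus trajectory analysis (end-to-end
    lengths, glycosidic geometry, conformer frequencies), multi-MODEL
    PDB/XYZ I/O, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
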