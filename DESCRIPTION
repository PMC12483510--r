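Package: pffpipe
Title: Classification of Hippocampal Place-Field Formation Events from
    Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for two-photon calcium imaging
    sessions recorded while an animal runs laps in a virtual linear corridor.
    The package preprocesses raw and neuropil fluorescence together with
    deconvolved activity (neuropil subtraction, noise gating of inferred
    events, rolling-median dF/F), detects spatially tuned cells with a
    Skaggs spatial-information bootstrap, demarcates significant place
    fields, temporally demarcates new place-field formation events, and
    classifies each event as BTSP-like (formation-lap amplitude gain plus
    an initial backward center-of-mass shift without continuous drift) or
    non-BTSP-like, with a misclassification bootstrap, solitary-transient
    detection, lap-by-lap population-vector correlograms, a place-field
    width model (running speed and landmark distance, leave-one-out
    explained variance), and pixel-level signal-isolation quality control.
    A seeded synthetic session generator with implanted, labelled events
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
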