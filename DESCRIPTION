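Package: smfretr
Title: Single-Molecule FRET Trace Analysis and Membrane Nanocluster Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-colour single-molecule FRET (smFRET)
    recordings of surface-immobilised receptors and for quantifying
    immunogold nanocluster sizes on membrane sheets. Covers channel
    registration and spot detection on two-channel TIRF movie stacks,
    aperture trace extraction with local background correction, donor
    leakage subtraction, photobleaching change-point detection, per-molecule
    gamma-factor estimation, the standard five-criterion trace selection,
    frame-wise FRET efficiency, per-molecule and ensemble histograms with
    two-Gaussian population fitting and bootstrap uncertainties, two-state
    hidden-Markov trace idealization, and single-linkage cluster-size
    statistics for gold-nanoparticle point patterns. A synthetic-data
    generator with known ground truth (photophysics, camera noise, spatial
    point patterns) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    data.table,
    jsonlite,
    minpack.lm,
    tiff,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
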