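Package: twistslide
Title: Ratchet Model of ATP-Driven Nucleosome Sliding by a Two-Lobe Translocase
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A reduced-coordinate model of active nucleosome repositioning by
    the ATPase translocase domain of Snf2-family chromatin remodelers. The
    nucleosome is described by 14 continuous histone-DNA contact indexes plus
    two translocase lobe registration coordinates; ATP consumption is emulated
    by switching the potential between apo, ATP-bound and ADP-bound parameter
    sets while propagating the coordinates by overdamped Langevin dynamics.
    The package ships the full analysis pipeline used to characterize the
    sliding mechanism: twist-defect timelines, metastable-state labeling,
    free-energy landscapes by Boltzmann inversion and umbrella reweighting,
    Markov state models with implied timescales and mean first-passage times,
    minimum-energy pathways on 2-D landscapes, and sequence-to-energetics
    mapping for positioning elements and defect-modulating repeats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
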