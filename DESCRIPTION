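Package: steeredFE
Title: Free-Energy Estimation from Steered Pulling Ensembles with
    Jarzynski-WHAM Reweighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify ligand-induced stabilization of an RNA
    base pair from ensembles of constant-velocity steered pulling
    simulations. Implements Jarzynski exponential work averaging along
    the pulling schedule, per-frame unbiased statistical weights by the
    combined Jarzynski/weighted-histogram (Hummer-Szabo) scheme,
    projection of free energies onto a-posteriori collective variables
    such as a discrete hydrogen-bond count, bound/unbound state free
    energy differences with trajectory-level bootstrap errors, and a
    two-system delta-delta-F comparison. Ships an overdamped Langevin
    toy simulator with an exact quadrature oracle so the full pipeline
    is testable end to end, plus a nearest-neighbor RNA duplex module
    (Turner parameter tables) for the helix-extension comparison that
    treats a bound ligand as one extra terminal AU pair. Reads and
    writes PLUMED-dialect COLVAR time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
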