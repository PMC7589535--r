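Package: fretsuite
Title: Optimal Design, Screening and Guidance for FRET-Assisted Structural Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and exploiting Foerster resonance energy transfer
    (FRET) experiments in integrative structural modeling of proteins.
    Simulates positional distributions of flexibly tethered dyes (accessible
    volumes) on coarse-grained grids, predicts inter-dye distance observables
    and their efficiency-propagated uncertainties, screens conformational
    ensembles with chi-squared statistics normalized to a fixed confidence
    level, selects maximally informative donor-acceptor pairs by expected
    model uncertainty or conditional-entropy criteria, drives
    Metropolis-Hastings annealed conformational sampling against FRET data,
    and emits restrained-mean-position pseudoatom restraints for
    FRET-restrained molecular dynamics in an AMBER-dialect restraint file.
    A synthetic hinge-protein generator provides self-contained benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
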