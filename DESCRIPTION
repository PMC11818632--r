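Package: p2dock
Title: Reproducible Post-Analysis of Protein-Protein Docking Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for the post-analysis of protein-protein
    docking experiments, built around the ataxin-3 interactome use case.
    Provides a validated, provenance-capturing pipeline engine with a module
    registry, pipeline diagrams and per-ligand block execution; interface
    residue detection for docked two-chain complexes via buried solvent
    accessible surface area (Shrake-Rupley) or distance cutoffs, plus a
    parser for PISA-style interface XML reports; consensus active/passive
    restraint derivation from multiple interface predictors; interacting
    region (IR) coverage scoring with a two-stage true-interactor
    classification over alternative structure sources; a wild-type versus
    polyglutamine-expanded differential interfacing statistic with
    categorical thresholds; contiguous-region detection and receptor domain
    annotation; protein list and tissue-expression filtering; and a
    synthetic fixture generator producing toy docked complexes with planted
    interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    bio3d,
    xml2,
    Rcpp,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
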