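Package: perilacunar
Title: Spatial Analysis of Perilacunar Remodeling in Cortical Bone SRuCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying perilacunar/canalicular remodeling (PLR) in
    synchrotron-radiation micro-computed tomography (SRuCT) volumes of cortical
    bone. Provides single-distance Paganin phase retrieval with a Fresnel
    forward simulator for validation, a reproducible osteocyte-lacuna and
    vascular-canal segmentation cascade, exact Euclidean distance transforms
    for lacuna-to-vasculature spatial statistics, distance-binned perilacunar
    mineralization profiles, cortical morphometry (BV/TV, Ct.Th, Lc.Dn), and
    nested mixed-model group comparisons with Hochberg and Benjamini-Hochberg
    corrections. A synthetic cortical-bone phantom generator with full ground
    truth makes every stage testable without access to beamline scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    data.table,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
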