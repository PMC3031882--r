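Package: cghclone
Title: Clonal Heterogeneity and Treatment Selection from Multi-Region Array CGH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intra-tumour genetic heterogeneity from
    multi-quadrant, multi-timepoint array-CGH copy-number profiles of cervical
    carcinomas under chemoradiotherapy. Implements median normalisation and
    circular binary segmentation of probe-level log2 ratios, copy-number state
    calling with amplification and homozygous-deletion thresholds, conversion
    of called segments to named aberration events in a telomere/centromere
    coordinate dialect, cross-sample event matching, homogeneous/heterogeneous
    event classification, per-case neighbour-joining phylogenies over sample
    genotypes with a diploid outgroup, trunk (early) event inference, and
    quadrant-by-timepoint subpopulation maps with clearance / persistence /
    replacement trajectory calls. A ground-truthed clone-mixture simulator
    (piecewise-constant clone genomes diluted by stroma, Gaussian probe noise)
    makes every stage testable, and machine-readable encodings of the study's
    clinical and rearrangement tables are packaged for fixture-mode analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
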