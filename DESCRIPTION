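Package: proteorhythm
Title: Differential Expression, Diurnal Rhythmicity and Network
    Connectivity for Case-Control Brain Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for postmortem case-control proteomics with a
    single time-of-death observation per subject. Provides covariate-adjusted
    moderated differential expression, synaptosome-versus-homogenate
    enrichment classification, fixed-period cosinor rhythm detection with
    permutation empirical p-values, differential rhythmicity (delta R
    squared) testing, weighted co-expression modules with module differential
    connectivity and neighborhood-based hub calling, rank-rank hypergeometric
    overlap maps, generic over-representation analysis against GMT gene-set
    collections, and a synthetic-cohort generator with recorded ground truth
    for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
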