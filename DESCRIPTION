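Package: polyQeval
Title: Evaluation of Predicted Structure Ensembles for Polyglutamine Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for judging predicted structure ensembles of
    polyglutamine-repeat protein fragments against partially resolved
    crystal references. Provides PDB chain import with construct mapping
    and unresolved-residue tracking, Kabsch superposition, TM-score and a
    sequence-independent structural aligner, exact-structure-overlap
    statistics (SO/ESO/ESOP), Kabsch-Sander secondary-structure assignment
    with position-frequency profiling over ensembles, multi-seed
    reproducibility and validity analyses with a normality-driven testing
    policy, and a synthetic backbone generator that emulates
    huntingtin-exon-1-like ensembles and reference masking so the whole
    pipeline can be exercised without running a structure predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
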