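Package: nedfold
Title: RNA Ensemble Diversity and the Morphology of RNA-Protein Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Thermodynamic-ensemble RNA secondary-structure analysis for
    predicting the morphology of RNA-protein condensates. Computes partition
    functions, base-pair probability matrices, minimum free energy and centroid
    structures, ensemble diversity and its length-normalised form (NED) under
    simple nearest-neighbour energy models; calls large disordered regions;
    classifies RNAs as sphere- or mesh-forming by dual NED thresholds; scans
    AU-rich elements and GC content; intersects CLIP peaks with 3'UTR
    intervals; simulates multivalent RNA-RNA dimerization networks; and ships
    rank-based statistics (tie-corrected Mann-Whitney Z with exact small-sample
    p, Kruskal-Wallis, Pearson) together with synthetic-data generators that
    exercise the whole pipeline without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
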