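Package: regraft
Title: Clade Placement on Fixed Backbones by Exhaustive Re-Grafting with
    AU, KH and SH Topology Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing the phylogenetic placement of a query clade
    (for example, a putatively transferred gene lineage) on a fixed backbone
    tree from protein alignments. Implements site-wise log-likelihoods under
    the WAG(+F)+I+Gamma4 model by the pruning algorithm, exhaustive
    enumeration of all re-graft positions of a pruned clade, topology tests
    (bootstrap proportion, Kishino-Hasegawa, Shimodaira-Hasegawa, and the
    approximately unbiased test via multiscale RELL bootstrap), maximum
    likelihood tree search with nonparametric bootstrap support, detection
    of taxon-group-specific insertion/deletion blocks, and a sequence
    simulator that generates alignments with planted clade placements and
    indel signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    seqinr,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
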