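Package: bcchet
Title: Multisite Tumor Heterogeneity Analysis for Proteomic and
    Transcriptomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra- and inter-tumor heterogeneity from multisite
    molecular profiles of the same lesion. Implements correlation-group
    heterogeneity statistics with a binned Bayesian misclassification
    probability, nested presence/absence intersection (Venn slice)
    decomposition with permutation expectations, CPM normalization and
    maximum pairwise fold-change screening for intra-patient heterogeneous
    genes with permutation overlap significance, and Jensen-Shannon
    distance calling of divergent expressed-allele positions. Includes a
    hierarchical synthetic-data generator emulating a 3-subtype x
    3-patient x 3-location cohort design for validation and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
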