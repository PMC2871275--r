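Package: taxrep
Title: Phylogenetic Representativeness of Taxon Samples from Taxonomic
    Distinctness
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assesses how well a sample of operational taxonomic units
    (OTUs) represents the taxonomic breadth of its group, using only a
    Linnean master taxonomy.  Computes average taxonomic distinctness
    (AvTD, Delta+), variation in taxonomic distinctness (VarTD, Lambda)
    and von Euler's index of imbalance under equal, unit or
    biodiversity-loss-proportional step-length weighting; tests samples
    against random-subsampling funnel distributions with one- or
    two-tailed randomization tests; and measures the stability of the
    results under simulated taxonomic revision (transfer, split and
    merge moves applied to the master list).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), vegan, igraph, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
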