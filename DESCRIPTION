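Package: ppigwas
Title: Network-Guided SNP-Set Association Testing with Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Set-based genome-wide association testing where the SNP sets are
    the k-hop neighborhoods of genes in a protein-protein interaction network.
    Each neighborhood's SNPs enter a linear mixed model as a random effect with
    a linear or inhomogeneous polynomial kernel, association is measured by a
    restricted-likelihood ratio, and calibrated empirical p-values are obtained
    from a combined circular SNP rotation and degree-preserving network
    permutation null, pooled across neighborhoods. Includes multiple-testing
    control across neighborhoods and traits, a block-LD genotype and scale-free
    network simulator with configurable causal architectures, and a
    precision-recall benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
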