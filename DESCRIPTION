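Package: hvdi
Title: Homologous Virus Diversity Index for Shotgun Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimation of bacteriophage community diversity from shotgun
    virome sequence data. Simulates viromes with controlled genotype
    richness and Pielou evenness, applies deterministic read quality
    filters, assembles reads by a greedy overlap-consensus strategy,
    clusters highly similar contigs into viral genotypes, and computes the
    Homologous Virus Diversity Index (HVDI) on the corrected contig
    spectrum using Shannon or Chao1 statistics, with rarefaction support.
    Also provides shared-contig permutation tests, assembly membership
    matrices, Bray-Curtis distances and principal coordinates analysis for
    comparing virome communities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    vegan,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
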