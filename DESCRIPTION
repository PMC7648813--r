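Package: snpdelim
Title: SNP-Based Species Delimitation by Fixed-Difference Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting candidate species (operational taxonomic
    units) from reduced-representation SNP genotypes. Implements staged
    quality filtering of DArT-style SNP matrices, principal coordinates
    analysis of inter-individual genetic distance, pairwise fixed-difference
    analysis with a sampling-error false-positive test and progressive
    amalgamation of populations into diagnosable units, private-allele
    counts, expected-heterozygosity randomization tests, Bayesian assignment
    of individuals to hybrid genotype-frequency classes (parentals, F1, F2
    and backcrosses) by Gibbs sampling, parent-offspring detection from
    opposing-homozygote counts, and supporting morphometric analyses
    (region summaries, sex-effect screening, Tukey-Kramer comparisons,
    canonical variate and principal component analysis). A synthetic-data
    generator emulates the multi-population sampling design, divergence,
    hybrids, kinship and genotyping artefacts these methods assume, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
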