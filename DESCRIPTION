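Package: apdtools
Title: Average Pairwise Dissimilarity for Individual Genomic Distinctness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the individual genomic distinctness of samples in a
    germplasm panel from genome-wide biallelic genotypes (SNPs or structural
    variants). Computes each sample's average pairwise dissimilarity (APD)
    against all other assayed samples, ranks samples and tabulates the overlap
    between rankings from different variant sets, situates APD-selected
    subsets in genotype PCA space via convex-hull area percentages, estimates
    individual inbreeding coefficients and their correlation with APD, and
    quantifies how many random variants a stable APD estimate requires.
    Includes VCF and PLINK 1 binary readers/writers, variant filtering by
    minor allele frequency and missingness, and a synthetic-panel generator
    with controlled inbreeding, population structure and genotyping noise for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
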