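Package: hapdeficit
Title: Missing-Homozygosity Scans for Recessive Lethal Haplotypes in
    Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects recessive lethal (and sublethal) haplotypes in
    artificial-insemination breeding populations from the deficit of
    homozygous animals relative to Mendelian expectation. Provides
    sliding-window haplotyping of phased SNP genotypes, exact
    Poisson-binomial deficit tests under trio (sire-dam-offspring) and
    pgp (sire-maternal-grandsire-offspring) designs with
    Benjamini-Yekutieli false discovery control, mixed-model association
    of haplotype diplotypes with deregressed breeding values using a
    genomic relationship matrix, linkage-disequilibrium based
    prioritization of candidate causal variants, and a gene-drop
    simulator of an AI breeding population with embedded recessive
    haplotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
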