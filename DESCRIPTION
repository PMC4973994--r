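Package: litgwas
Title: Literature-Informed GWAS of Gestational Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a literature-informed genome-wide
    association workflow for continuous gestational age: genotype and sample
    quality control (missingness, heterozygosity, relatedness, Hardy-Weinberg
    exact test, PCA ancestry outliers, genomic inflation), per-SNP association
    under additive, recessive and dominant genetic models with adaptive
    permutation empirical p-values and per-SNP min-p combination, greedy LD
    clumping, abstract text-mining of keyword gene-sets with blacklist and
    acronym disambiguation, and interval-based gene-set enrichment against
    SNP-density-matched random intervals. A synthetic-data module generates
    LD-blocked genotypes, a bimodal case-oversampled phenotype, gene
    annotations and a labelled abstract corpus so that every stage of the
    pipeline is verifiable offline.
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
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
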