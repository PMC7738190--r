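Package: poolscan
Title: Pool-Seq Population Differentiation Scans and Inversion Haplotype Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting ecological adaptation from pooled whole-genome
    sequencing of many populations. Implements effective-allele-count (N_eff)
    corrected allele frequencies, partitioning of markers into undifferentiated
    and highly differentiated sets with spatial thinning and principal component
    analysis, superpool 2x2 chi-square genome scans with genomic-control
    (lambda) inflation correction and Bonferroni thresholding, clustering of
    significant SNPs into independent loci with replication across contrasts,
    pool-based F_ST in sliding windows, Nei genetic distances with
    neighbor-joining and bootstrap consensus trees, nucleotide diversity and
    diagnostic-marker haplotype frequencies at inversion-like structural
    variants, and a Balding-Nichols synthetic pool-seq generator with planted
    selected loci for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
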