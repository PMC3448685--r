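Package: misnpscan
Title: Genome-Wide Scan for pri-miRNA SNP Effects and miSNP x 3'UTR-SNP
    Interactions on Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An eQTL analysis pipeline for assessing how SNPs located in
    pri-miRNA sequences (miSNPs) influence gene expression, marginally and
    through pairwise interaction with SNPs in 3'UTR regions (3utrSNPs).
    Implements genotype quality control (MAF, call rate, exact
    Hardy-Weinberg test), two-locus haplotype frequency estimation by EM
    with derived linkage-disequilibrium statistics (D, D', r2) and
    LD-proxy selection, additive cis/trans association scans with
    conditional (eSNP- or mediator-adjusted) models, a pairwise
    interaction scan with a variance-prioritized weighted-Bonferroni
    correction in which each interaction p-value is weighted by the
    Levene test for expression-variance heterogeneity across 3utrSNP
    genotypes, two-SNP haplotype-effect regression on expected haplotype
    dosages with an effect-homogeneity test, and a synthetic
    genotype-expression generator with known ground truth for calibrating
    and validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
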