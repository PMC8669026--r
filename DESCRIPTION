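Package: grqtl
Title: Sex-Stratified Genetic Regulation of the Glucocorticoid Receptor
    Transcriptome Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genetic regulation of the blood
    transcriptome response to glucocorticoid receptor (GR) stimulation with
    dexamethasone, with full support for sex-stratified analyses. Implements
    paired baseline/post-stimulation differential expression, cis-eQTL and
    cis-meQTL mapping with a two-stage multiple-testing correction
    (per-probe Westfall-Young maxT permutations followed by
    Benjamini-Hochberg over LD-clumped tag SNPs), minor-allele-frequency
    matched permutation enrichment against genomic annotations and GWAS SNP
    sets, gene-set overlap tests, and a weighted allele-dosage
    transcriptional sensitivity profile score (TSPS). A synthetic-data
    module generates genotypes with block LD structure, paired expression,
    methylation, covariates and annotation fixtures with known ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
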