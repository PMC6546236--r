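Package: edconsensus
Title: Consensus Detection of A-to-I RNA Editing from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects adenosine-to-inosine (A-to-I) RNA editing sites from
    aligned RNA-seq reads by running three independent calling strategies --
    a strict hard-filter cascade, a mutual-information allelic-linkage test
    against known SNPs, and editing-island clustering -- intersecting their
    calls within each biological replicate and taking the union across
    replicates of a cell line. Downstream tools classify consensus sites by
    Alu repeat and gene-body context, assign edited genes, partition sites
    and genes by cell-line specificity, count genomic variants per gene from
    DNA-seq calls, and test hypergeometric enrichment of differentially
    expressed genes among edited genes. A synthetic-data generator emulates
    the multi-cell-line, multi-replicate study design (clustered editing in
    inverted Alu-like repeats, phased heterozygous SNPs as confounders, an
    ADAR-activity scalar, and a two-condition expression matrix) so the full
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
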