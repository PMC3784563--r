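Package: peakscape
Title: ChIP-Seq Peak Annotation, TSS Enrichment and miRNA Target-Site
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of protein-chromatin ChIP-seq peak calls
    integrated with expression profiling. Provides validation-driven FDR
    cutoff selection and peak filtering, genome feature partitioning
    (promoter, UTRs, coding exons, introns, flanks) with exact binomial
    enrichment statistics, repeat-class and per-chromosome density
    analyses with regression on genomic covariates, strand-aware TSS
    distance profiling and co-occurrence with chromatin marks,
    hypergeometric gene-set overlap tests between bound and responsive
    genes with a 1-bp positional enrichment scan around TSSs, and miRNA
    seed-match target-site enrichment in bound sequences against
    length-matched random control regions, including k-mer consensus
    motif discovery. A seeded synthetic-data generator emits a complete
    toy dataset (genome, gene models, peaks, marks, repeats, expression
    and miRNA sequences) with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0),
    GenomicRanges
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
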