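# Gene-model I/O, coordinate conversions, genome partitioning and
# strand-aware TSS arithmetic.

test_that("BED12 records map onto validated gene models", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tg1\t0\t+\t1099\t1900\t0\t2\t201,200\t0,801",
             bed)
  g <- readGeneModels(bed)
  expect_equal(mcols(g)$gene_id, "g1")
  # 0-based half-open 999..2000 becomes 1-based closed 1000..2000
  expect_equal(start(g), 1000)
  expect_equal(end(g), 2000)
  ex <- mcols(g)$exons[[1]]
  expect_equal(start(ex), c(1000, 1801))
  expect_equal(end(ex), c(1200, 2000))
  expect_equal(mcols(g)$cds_start, 1100)
  expect_equal(mcols(g)$cds_end, 1900)
})

test_that("GTF input is taken as 1-based and assembled per transcript", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ttoy\texon\t1000\t1200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\ttoy\texon\t1800\t2000\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\ttoy\tCDS\t1100\t1200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\ttoy\tCDS\t1800\t1900\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')), gtf)
  g <- readGeneModels(gtf)
  expect_equal(start(g), 1000)
  expect_equal(end(g), 2000)
  expect_equal(mcols(g)$cds_start, 1100)
  expect_equal(mcols(g)$cds_end, 1900)
  expect_equal(length(mcols(g)$exons[[1]]), 2L)
})

test_that("malformed and invalid gene models are rejected with context", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tg1\t0\t+\t1099\t1900\t0\t2\t201,200\t0,801",
               "chr1\t10\t20"), bad)
  expect_error(readGeneModels(bad), "line 2")
  # exon outside transcript bounds
  expect_error(
    GeneModels("g1", "chr1", 1000, 2000, "+",
               list(IRanges::IRanges(900, 1200))),
    "exon outside transcript")
  expect_error(
    GeneModels("g1", "chr1", 1000, 2000, "+", list(IRanges::IRanges())),
    "without exons")
  expect_error(
    GeneModels("g1", "chr1", 1000, 2000, "*",
               list(IRanges::IRanges(1000, 1200))),
    "strand")
})

test_that("gene models survive a BED12 write/read round trip", {
  genes <- genes_from_list(list(
    list(chrom = "chr1", strand = "+", tx_start = 1000, tx_end = 2000,
         exons = list(c(1000, 1200), c(1800, 2000)),
         cds_start = 1100, cds_end = 1900),
    list(chrom = "chr2", strand = "-", tx_start = 500, tx_end = 1500,
         exons = list(c(500, 800), c(1200, 1500)),
         cds_start = NA, cds_end = NA)))
  f <- tempfile(fileext = ".bed")
  writeGeneModels(genes, f)
  back <- readGeneModels(f)
  expect_equal(mcols(back)$gene_id, mcols(genes)$gene_id)
  expect_equal(start(back), start(genes))
  expect_equal(end(back), end(genes))
  expect_equal(as.character(strand(back)), as.character(strand(genes)))
  expect_equal(mcols(back)$cds_start, mcols(genes)$cds_start)
  expect_equal(mcols(back)$cds_end, mcols(genes)$cds_end)
  for (i in 1:2)
    expect_equal(as.data.frame(mcols(back)$exons[[i]]),
                 as.data.frame(mcols(genes)$exons[[i]]))
})

test_that("signed TSS distance is strand-aware with 0 at the TSS base", {
  gp <- genes_from_list(list(
    list(chrom = "chr1", strand = "+", tx_start = 1000, tx_end = 2000,
         exons = list(c(1000, 2000)), cds_start = NA, cds_end = NA)))
  expect_equal(signedTssDistance(gp, 1100), 100)
  expect_equal(signedTssDistance(gp, 1000), 0)
  expect_equal(signedTssDistance(gp, 900), -100)
  # minus-strand gene with last transcribed base at 2000: position 1900 is
  # 100 bp downstream
  gm <- genes_from_list(list(
    list(chrom = "chr1", strand = "-", tx_start = 1000, tx_end = 2000,
         exons = list(c(1000, 2000)), cds_start = NA, cds_end = NA)))
  expect_equal(signedTssDistance(gm, 1900), 100)
  expect_equal(signedTssDistance(gm, 2000), 0)
})

test_that("minus-strand distances mirror a reflected plus-strand gene", {
  # property: d_minus(gene, p) == -d_plus(mirror(gene), mirror(p))
  L <- 10000
  set.seed(42)
  for (rep in 1:20) {
    s <- sample(2000:6000, 1); e <- s + sample(500:2000, 1)
    gm <- genes_from_list(list(
      list(chrom = "chr1", strand = "-", tx_start = s, tx_end = e,
           exons = list(c(s, e)), cds_start = NA, cds_end = NA)))
    gp <- genes_from_list(list(
      list(chrom = "chr1", strand = "+", tx_start = L - e + 1,
           tx_end = L - s + 1, exons = list(c(L - e + 1, L - s + 1)),
           cds_start = NA, cds_end = NA)))
    p <- sample(1:L, 5)
    expect_equal(signedTssDistance(gm, p),
                 signedTssDistance(gp, L - p + 1))
  }
})

test_that("an empty gene set partitions to all-intergenic", {
  sizes <- toy_sizes(chr1 = 5000, chr2 = 3000)
  fm <- partitionGenome(GeneModels(character(), character(), integer(),
                                   integer(), character(), list()),
                        sizes, flank_width = 500)
  comp <- genomeComposition(fm)
  expect_equal(unname(comp[["intergenic"]]), 8000)
  expect_equal(sum(comp), 8000)
  expect_error(partitionGenome(GeneModels(character(), character(),
                                          integer(), integer(),
                                          character(), list()),
                               sizes, flank_width = 0), "flank_width")
})

test_that("partitioning matches the per-base oracle, including overlaps", {
  sizes <- toy_sizes(chr1 = 10000)
  gene_list <- list(
    # + strand coding gene: 2 exons, CDS inside
    list(chrom = "chr1", strand = "+", tx_start = 1001, tx_end = 2000,
         exons = list(c(1001, 1200), c(1801, 2000)),
         cds_start = 1101, cds_end = 1900),
    # - strand gene whose promoter (downstream of 4500 in genomic terms)
    # overlaps the intron/body territory of a third gene
    list(chrom = "chr1", strand = "-", tx_start = 3500, tx_end = 4500,
         exons = list(c(3500, 3700), c(4300, 4500)),
         cds_start = 3600, cds_end = 4400),
    # + strand non-coding gene spanning the second gene's promoter zone
    list(chrom = "chr1", strand = "+", tx_start = 4600, tx_end = 5600,
         exons = list(c(4600, 4800), c(5400, 5600)),
         cds_start = NA, cds_end = NA))
  genes <- genes_from_list(gene_list, sizes)
  fm <- partitionGenome(genes, sizes, flank_width = 500)
  labs <- as.character(fm@labels$chr1)
  oracle <- vapply(1:10000, function(p)
    oracle_label_at(gene_list, "chr1", p, flank = 500), "")
  expect_identical(labs, oracle)
  # composition conserves the genome length
  expect_equal(sum(genomeComposition(fm)), 10000)
  # the second gene's promoter (4501..5000) wins over gene 3's body
  expect_true(all(labs[4501:5000] == "promoter"))
})

test_that("interval location respects midpoints and normalizes bp modes", {
  sizes <- toy_sizes(chr1 = 10000)
  gene_list <- list(
    list(chrom = "chr1", strand = "+", tx_start = 1001, tx_end = 2000,
         exons = list(c(1001, 1200), c(1801, 2000)),
         cds_start = 1101, cds_end = 1900))
  genes <- genes_from_list(gene_list, sizes)
  fm <- partitionGenome(genes, sizes, flank_width = 500)
  # entirely intergenic interval
  expect_equal(locateInterval(fm, GRanges("chr1", IRanges(8000, 8100))),
               "intergenic")
  # straddles promoter (501..1000) and 5' UTR; midpoint in the promoter
  gr <- GRanges("chr1", IRanges(901, 1050))
  expect_equal(locateInterval(fm, gr), "promoter")
  comp <- locateInterval(fm, gr, mode = "bp_composition")
  expect_equal(sum(comp[1, ]), 1.0)
  expect_equal(unname(comp[1, "promoter"]), 100 / 150)
  expect_error(locateInterval(fm, GRanges("chrX", IRanges(1, 10))),
               "unknown chromosome")
  expect_error(locateInterval(fm, GRanges("chr1", IRanges(9990, 10050))),
               "outside chromosome")
})

test_that("chromosome sizes reader validates its input", {
  f <- tempfile()
  writeLines(c("chr1\t1000", "chr2\t500"), f)
  si <- readChromSizes(f)
  expect_equal(unname(GenomeInfoDb::seqlengths(si)), c(1000L, 500L))
  writeLines(c("chr1\t1000", "chr1\t500"), f)
  expect_error(readChromSizes(f), "duplicated")
  writeLines(c("chr1\t-5"), f)
  expect_error(readChromSizes(f), "positive")
})
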