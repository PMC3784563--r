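# Composition statistics, enrichment tests, density regressions and
# interval overlap summaries.

# a 10 kb single-chromosome map with one coding gene; promoter 501..1000
toy_map <- function() {
  sizes <- toy_sizes(chr1 = 10000)
  genes <- genes_from_list(list(
    list(chrom = "chr1", strand = "+", tx_start = 1001, tx_end = 2000,
         exons = list(c(1001, 1200), c(1801, 2000)),
         cds_start = 1101, cds_end = 1900)), sizes)
  partitionGenome(genes, sizes, flank_width = 500)
}

test_that("a class covering half the genome with half the peaks is flat", {
  sizes <- toy_sizes(chr1 = 1000)
  genes <- genes_from_list(list(
    # non-coding single-exon gene covering 1..500: coding_exon class
    list(chrom = "chr1", strand = "+", tx_start = 1, tx_end = 500,
         exons = list(c(1, 500)), cds_start = NA, cds_end = NA)), sizes)
  fm <- partitionGenome(genes, sizes, flank_width = 1)
  # promoter/flank of width 1 are negligible but present; place peaks
  pk <- peaks_gr("chr1", c(100, 200, 300, 400, 450,
                           600, 700, 800, 900, 950),
                 c(101, 201, 301, 401, 451,
                   601, 701, 801, 901, 951))
  enr <- featureComposition(pk, fm)
  ce <- enr[enr$feature == "coding_exon", ]
  expect_equal(ce$observed_count, 5)
  expect_equal(ce$ratio, 0.5 / ce$genome_fraction * 1, tolerance = 1e-12)
  expect_equal(sum(enr$observed_fraction), 1)
})

test_that("enrichment p-values match exhaustive binomial enumeration", {
  # the spec-style 9-of-10 peaks in a 10%-of-genome class
  expect_equal(binom.test(9, 10, 0.1)$p.value,
               oracle_binom_two_sided(9, 10, 0.1), tolerance = 1e-12)
  # broad sweep: n <= 20, assorted p0
  for (n in c(5, 12, 20))
    for (p0 in c(0.1, 0.25, 0.5, 0.9))
      for (k in unique(c(0, 1, floor(n / 2), n))) {
        expect_equal(binom.test(k, n, p0)$p.value,
                     oracle_binom_two_sided(k, n, p0),
                     tolerance = 1e-12,
                     info = sprintf("k=%d n=%d p0=%g", k, n, p0))
      }
})

test_that("feature enrichment reports ratios against the genome", {
  fm <- toy_map()
  # 9 peaks in the promoter (501..1000, 5% of the genome), 1 elsewhere
  pk <- peaks_gr("chr1", c(seq(510, 910, by = 50), 5000),
                 c(seq(520, 920, by = 50), 5100))
  enr <- featureComposition(pk, fm)
  prom <- enr[enr$feature == "promoter", ]
  expect_equal(prom$observed_count, 9)
  expect_equal(prom$ratio, 0.9 / 0.05, tolerance = 1e-12)
  expect_equal(prom$p_value,
               oracle_binom_two_sided(9, 10, 0.05), tolerance = 1e-12)
  expect_true(all(is.finite(enr$log10_p[!is.na(enr$p_value)])))
  # complement consistency: intergenic underrepresented when promoter is
  # overrepresented and both are interior
  expect_lt(enr$ratio[enr$feature == "intergenic"], 1)
})

test_that("uniform peaks show no enrichment beyond binomial noise", {
  fm <- toy_map()
  set.seed(31)
  n <- 400
  st <- sample.int(9900, n)
  pk <- peaks_gr("chr1", st, st + 99)
  enr <- featureComposition(pk, fm)
  for (i in seq_len(nrow(enr))) {
    gf <- enr$genome_fraction[i]
    if (gf <= 0 || gf >= 1) next
    band <- qbinom(c(0.005, 0.995), n, gf)
    expect_gte(enr$observed_count[i], band[1])
    expect_lte(enr$observed_count[i], band[2])
  }
})

test_that("repeat composition apportions peak bases and warns on overlap", {
  gf <- c(SINE = 0.1, LINE = 0.2)
  pk <- peaks_gr("chr1", 1001, 2000)   # one 1 kb peak
  # no repeats: all non-repetitive
  rc0 <- repeatComposition(pk, GRanges(), gf)
  expect_equal(rc0$observed_fraction[rc0$feature == "non_repetitive"], 1)
  # half the peak covered by a SINE
  reps <- GRanges("chr1", IRanges(1501, 2000))
  mcols(reps)$class <- "SINE"
  rc <- repeatComposition(pk, reps, gf)
  expect_equal(rc$observed_fraction[rc$feature == "SINE"], 0.5)
  expect_equal(sum(rc$observed_fraction), 1)
  # overlapping annotations resolve to the first-listed class
  reps2 <- GRanges("chr1", IRanges(c(1501, 1601), c(2000, 1900)))
  mcols(reps2)$class <- c("SINE", "LINE")
  expect_warning(rc2 <- repeatComposition(pk, reps2, gf), "first-listed")
  expect_equal(rc2$observed_fraction[rc2$feature == "SINE"], 0.5)
  expect_equal(rc2$observed_fraction[rc2$feature == "LINE"], 0)
})

test_that("density tables compute covariates and validate completeness", {
  sizes <- toy_sizes(chr1 = 3e6, chr2 = 1e6)
  pk <- peaks_gr(rep("chr1", 30), (1:30) * 1000, (1:30) * 1000 + 99,
                 sizes = sizes)
  genes <- genes_from_list(list(
    list(chrom = "chr1", strand = "+", tx_start = 1e5, tx_end = 1e5 + 999,
         exons = list(c(1e5, 1e5 + 999)), cds_start = NA, cds_end = NA)),
    sizes)
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("G", 100),
                                       chr2 = strrep("A", 100)))
  # all-G sequence: GC% = 100
  tab <- buildDensityTable(pk, genes, sizes, genome = genome,
                           repeat_pct = c(chr1 = 10, chr2 = 20))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$peak_density[tab$chrom == "chr1"], 1.0)  # 30 / 3 Mb
  expect_equal(tab$gc_pct, c(100, 0))
  expect_error(buildDensityTable(pk, genes, sizes,
                                 gc = c(chr1 = 50),
                                 repeat_pct = c(chr1 = 1, chr2 = 2)),
               "chr2")
})

test_that("regressions recover exact fits and the closed-form solution", {
  # exactly linear data
  tab <- data.frame(chrom = paste0("c", 1:6), length = 1e6,
                    peak_density = 2 * (1:6) + 1, gene_density = 1:6,
                    gc_pct = c(40, 42, 41, 43, 40, 44),
                    repeat_pct = c(30, 31, 29, 33, 35, 30))
  r <- suppressWarnings(regressPeakDensity(tab, covariates = "gene_density"))
  expect_equal(r$simple$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$simple$slope, 2, tolerance = 1e-12)
  # closed-form normal equations on a 5-row table
  tab5 <- data.frame(peak_density = c(3.1, 4.9, 7.2, 8.8, 11.1),
                     gene_density = 1:5)
  r5 <- regressPeakDensity(tab5, covariates = "gene_density")
  X <- cbind(1, tab5$gene_density)
  beta <- solve(t(X) %*% X, t(X) %*% tab5$peak_density)
  expect_equal(r5$simple$slope, beta[2], tolerance = 1e-12)
  # seeded recovery: slope within 3 SE of the generating coefficient
  set.seed(13)
  gd <- runif(24, 1, 10)
  tabr <- data.frame(peak_density = 1.5 * gd + rnorm(24, 0, 0.5),
                     gene_density = gd,
                     gc_pct = runif(24, 35, 55),
                     repeat_pct = runif(24, 20, 50))
  rr <- regressPeakDensity(tabr)
  srow <- rr$simple[rr$simple$covariate == "gene_density", ]
  mrow <- rr$multiple[rr$multiple$term == "gene_density", ]
  expect_lt(abs(mrow$estimate - 1.5), 3 * mrow$std_error)
  expect_gt(srow$r_squared, 0.8)
})

test_that("overlap fractions agree with the quadratic-scan oracle", {
  pk <- peaks_gr("chr1", c(100, 300, 900), c(200, 400, 1000))
  # identity
  self <- overlapFraction(pk, pk)
  expect_equal(self$fraction, 1)
  expect_equal(self$jaccard, 1)
  # disjoint
  far <- GRanges("chr1", IRanges(5000, 6000))
  expect_equal(overlapFraction(pk, far)$fraction, 0)
  # mixed toy case vs oracle
  set.seed(3)
  q <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                  start = sample(1:5000, 40))
  q$end <- q$start + sample(50:500, 40, TRUE)
  r <- data.frame(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                  start = sample(1:5000, 15))
  r$end <- r$start + sample(50:500, 15, TRUE)
  got <- overlapFraction(GRanges(q$chrom, IRanges(q$start, q$end)),
                         GRanges(r$chrom, IRanges(r$start, r$end)))
  expect_equal(got$fraction, oracle_overlap_fraction(q, r))
})
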