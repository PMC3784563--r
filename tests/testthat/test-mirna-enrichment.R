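# Seed-match site prediction, matched-control sampling, per-miRNA
# enrichment calls and consensus motif analysis.

test_that("seed rules derive the expected DNA match motifs", {
  m <- "UAGCUUAUCAGACUGAUGUUGA"
  # 7mer-m8: seed positions 2-8 = AGCUUAU -> DNA match ATAAGCT
  expect_equal(as.character(seedMatchMotif(m)), "ATAAGCT")
  expect_equal(as.character(seedMatchMotif(m, "6mer")), "TAAGCT")
  expect_equal(as.character(seedMatchMotif(m, "8mer")), "ATAAGCTA")
  expect_error(seedMatchMotif("ACGUACG"), "at least 8")
  expect_error(seedMatchMotif("ACGTACGT"), "RNA alphabet")
})

test_that("site counting scans both strands, overlaps included, N inert", {
  m <- "UAGCUUAUCAGACUGAUGUUGA"   # match motif ATAAGCT
  expect_equal(predictTargetSites("GGATAAGCTGG", m), 1L)
  # same motif once per strand -> 2 sites
  both <- paste0("ATAAGCT", "CCCCC", "AGCTTAT")  # fwd + revcomp
  expect_equal(predictTargetSites(both, m), 2L)
  expect_equal(predictTargetSites("", m), 0L)
  expect_equal(predictTargetSites(strrep("N", 50), m), 0L)
  expect_equal(predictTargetSites("ATAAGC", m), 0L)  # shorter than motif
  # overlapping occurrences all count
  mm <- "UAAAAAAAACGCGCGCGCGCGC"   # seed 2-8 AAAAAAA -> match TTTTTTT
  expect_equal(predictTargetSites("TTTTTTTTT", mm),
               oracle_count_sites("TTTTTTTTT", "TTTTTTT"))
  expect_equal(predictTargetSites("TTTTTTTTT", mm), 3L)
  # strand symmetry: reverse-complementing the sequence preserves counts
  set.seed(19)
  for (rep in 1:10) {
    s <- paste0(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(predictTargetSites(s, m), predictTargetSites(rc, m))
    expect_equal(predictTargetSites(s, m), oracle_count_sites(s, "ATAAGCT"))
  }
})

test_that("matched controls preserve length and chromosome, avoid peaks", {
  sizes <- toy_sizes(chr1 = 100000, chr2 = 60000)
  pk <- peaks_gr(c("chr1", "chr1", "chr2"), c(1000, 5000, 2000),
                 c(1099, 5199, 2299), sizes = sizes)
  c1 <- sampleMatchedControls(pk, sizes, seed = 4)
  expect_equal(width(c1), width(pk))
  expect_equal(as.character(seqnames(c1)), as.character(seqnames(pk)))
  # determinism
  c2 <- sampleMatchedControls(pk, sizes, seed = 4)
  expect_identical(start(c1), start(c2))
  # no control overlaps any peak (quadratic scan)
  q <- data.frame(chrom = as.character(seqnames(c1)), start = start(c1),
                  end = end(c1))
  r <- data.frame(chrom = as.character(seqnames(pk)), start = start(pk),
                  end = end(pk))
  expect_equal(oracle_overlap_fraction(q, r), 0)
  # impossible placements error with the peak named
  tiny <- toy_sizes(chr1 = 120)
  wide <- peaks_gr("chr1", 1, 100, sizes = tiny)
  expect_error(sampleMatchedControls(wide, tiny, seed = 1,
                                     max_attempts = 50),
               "peak 1")
})

test_that("GC matching constrains control composition when requested", {
  sizes <- toy_sizes(chr1 = 10000)
  # genome: GC-rich first half, AT-rich second half
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("GC", 2500), strrep("AT", 2500))))
  pk <- peaks_gr("chr1", 101, 300, sizes = sizes)   # pure GC
  ctrl <- sampleMatchedControls(pk, sizes, seed = 2, gc_tol = 0.05,
                                genome = genome)
  gc <- Biostrings::letterFrequency(extractSequences(genome, ctrl)[[1]],
                                    c("G", "C"))
  expect_gte(sum(gc) / width(ctrl), 0.95)
})

test_that("identical peak and control sequences give an all-neutral table", {
  set.seed(6)
  seqs <- Biostrings::DNAStringSet(vapply(1:10, function(i)
    paste0(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""), ""))
  mir <- Biostrings::RNAStringSet(vapply(1:5, function(i)
    paste0(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""), ""))
  names(mir) <- paste0("m", 1:5)
  tab <- mirnaEnrichmentTable(seqs, seqs, mir)
  expect_true(all(tab$call == "neutral"))
  expect_true(all(tab$ratio[!is.na(tab$ratio)] == 1))
  expect_true(all(tab$p_value == 1))
})

test_that("implanted miRNAs are called enriched; p matches enumeration", {
  set.seed(8)
  n_seq <- 30
  base <- vapply(seq_len(n_seq), function(i)
    paste0(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""), "")
  peak_seqs <- Biostrings::DNAStringSet(base)
  ctrl_seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_seq), function(i)
    paste0(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""), ""))
  mir <- Biostrings::RNAStringSet(vapply(1:50, function(i)
    paste0(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""), ""))
  names(mir) <- sprintf("m%02d", 1:50)
  imp <- implantSeedSites(peak_seqs, mir[1:5], implant_rate = 1, seed = 3)
  tab <- mirnaEnrichmentTable(imp$sequences, ctrl_seqs, mir)
  expect_true(all(tab$call[1:5] == "enriched"))
  expect_lt(sum(tab$call[6:50] == "enriched"), 3)
  # binomial p equals exhaustive enumeration for small totals
  small <- tab[tab$sites_peaks + tab$sites_controls <= 20 &
                 tab$sites_peaks + tab$sites_controls > 0, ]
  expect_gt(nrow(small), 0)
  for (i in seq_len(nrow(small)))
    expect_equal(small$p_value[i],
                 oracle_binom_two_sided(small$sites_peaks[i],
                                        small$sites_peaks[i] +
                                          small$sites_controls[i], 0.5),
                 tolerance = 1e-12)
  # zero sites anywhere: neutral with p = 1
  blank <- Biostrings::DNAStringSet(strrep("A", 100))
  mirC <- Biostrings::RNAStringSet(c(z = "UGGGCCCGGGCCCGGGCCCGGG"))
  tabz <- mirnaEnrichmentTable(blank, blank, mirC)
  expect_equal(tabz$call, "neutral")
  expect_equal(tabz$p_value, 1)
  expect_true(is.na(tabz$ratio))
})

test_that("motif discovery merges one-mismatch k-mers into IUPAC consensi", {
  seqs <- Biostrings::RNAStringSet(c(
    "GGGAGUGCAGGGGGGGGG",      # AGUGCA x1
    "CCCAGUGCACCCCCCCCC",      # AGUGCA x1
    "UUUAGUGCAUUUUUUUUU",      # AGUGCA x1
    "GGGAGUGCUGGGGGGGGG",      # AGUGCU x1
    "AGUGCUAAAGGAGUGCUG"))     # AGUGCU x2
  res <- discoverMotif(seqs, k = 6)
  expect_equal(res$consensus, "AGUGCW")
  expect_equal(res$n_containing, 5L)
  expect_equal(res$n_with_two, 1L)
  expect_equal(res$total_occurrences, 6)
  # all counts verified by the exhaustive scan oracle
  occ <- oracle_consensus_counts(as.character(seqs), "AGUGCW")
  expect_equal(sum(occ >= 1), res$n_containing)
  expect_equal(sum(occ >= 2), res$n_with_two)
  expect_equal(sum(occ), res$total_occurrences)
  # single sequence: the motif is itself
  one <- discoverMotif(Biostrings::RNAStringSet("AGUGCA"), k = 6)
  expect_equal(one$consensus, "AGUGCA")
  expect_equal(one$n_containing, 1L)
  expect_equal(one$total_occurrences, 1)
  expect_error(discoverMotif(Biostrings::RNAStringSet()), "empty")
})

test_that("motif discovery counts equal the oracle on random inputs", {
  set.seed(27)
  for (rep in 1:5) {
    seqs <- vapply(1:12, function(i)
      paste0(sample(c("A", "C", "G", "U"), sample(15:30, 1), TRUE),
             collapse = ""), "")
    res <- discoverMotif(Biostrings::RNAStringSet(seqs), k = 5)
    occ <- oracle_consensus_counts(seqs, res$consensus)
    expect_equal(sum(occ >= 1), res$n_containing)
    expect_equal(sum(occ >= 2), res$n_with_two)
    expect_equal(sum(occ), res$total_occurrences)
  }
})

test_that("motif homology is ungapped percent identity, maximized", {
  expect_equal(motifHomology(c("AGUGCU", "AGUGCA"), "AGUGUU"),
               100 * 5 / 6, tolerance = 1e-9)
  expect_equal(motifHomology("ACGUAC", "ACGUAC"), 100)
  expect_equal(motifHomology("AAAAAA", "UUUUUU"), 0)
  expect_error(motifHomology("ACGU", "ACGUA"), "length")
})

test_that("miRNA FASTA input accepts T with a warning", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">m1", "ACGTACGTACGTACGTACGTAC"), f)
  expect_warning(m <- readMiRNAs(f), "converting to U")
  expect_equal(as.character(m[[1]]), "ACGUACGUACGUACGUACGUAC")
})
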