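# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive and separate from the implementation paths they check.

# Per-base feature labeler: applies the precedence rule independently at a
# single position, from a plain list-of-lists gene description
# (chrom, strand, tx_start, tx_end, exons (list of c(start, end)),
#  cds_start, cds_end; all 1-based closed).
oracle_label_at <- function(genes, chrom, pos, flank) {
  in_any <- function(test) any(vapply(genes, test, TRUE))
  on_chrom <- Filter(function(g) g$chrom == chrom, genes)
  in_exon_part <- function(g, lo, hi, p) {
    if (is.na(lo) || lo > hi) return(FALSE)
    any(vapply(g$exons, function(e)
      p >= max(e[1], lo) && p <= min(e[2], hi), TRUE))
  }
  for (g in on_chrom) {   # promoter
    tss <- if (g$strand == "+") g$tx_start else g$tx_end
    prom <- if (g$strand == "+") c(tss - flank, tss - 1)
            else c(tss + 1, tss + flank)
    if (pos >= prom[1] && pos <= prom[2]) return("promoter")
  }
  for (g in on_chrom) {   # 5' UTR
    if (is.na(g$cds_start)) next
    r <- if (g$strand == "+") c(g$tx_start, g$cds_start - 1)
         else c(g$cds_end + 1, g$tx_end)
    if (in_exon_part(g, r[1], r[2], pos)) return("five_prime_utr")
  }
  for (g in on_chrom) {   # coding exon (all exons when no CDS)
    lo <- if (is.na(g$cds_start)) g$tx_start else g$cds_start
    hi <- if (is.na(g$cds_start)) g$tx_end else g$cds_end
    if (in_exon_part(g, lo, hi, pos)) return("coding_exon")
  }
  for (g in on_chrom) {   # intron: inside transcript, outside all exons
    if (pos >= g$tx_start && pos <= g$tx_end &&
        !any(vapply(g$exons, function(e)
          pos >= e[1] && pos <= e[2], TRUE)))
      return("intron")
  }
  for (g in on_chrom) {   # 3' UTR
    if (is.na(g$cds_start)) next
    r <- if (g$strand == "+") c(g$cds_end + 1, g$tx_end)
         else c(g$tx_start, g$cds_start - 1)
    if (in_exon_part(g, r[1], r[2], pos)) return("three_prime_utr")
  }
  for (g in on_chrom) {   # 3' flank
    r <- if (g$strand == "+") c(g$tx_end + 1, g$tx_end + flank)
         else c(g$tx_start - flank, g$tx_start - 1)
    if (pos >= r[1] && pos <= r[2]) return("three_prime_flank")
  }
  "intergenic"
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial summation.
oracle_hyper_upper <- function(k, N, K, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Hypergeometric upper tail by exhaustive enumeration over all draws of
# size n from a universe with K marked elements (combn-based; tiny N only).
oracle_hyper_enum <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# Two-sided exact binomial p: sum of all outcome probabilities not larger
# than the observed one (with the conventional 1 + 1e-7 relative guard).
oracle_binom_two_sided <- function(k, n, p0) {
  pmf <- exp(lchoose(n, 0:n) + (0:n) * log(p0) + (n - 0:n) * log1p(-p0))
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Quadratic-scan overlap: fraction of query intervals (data.frame
# chrom/start/end) sharing >= 1 bp with any region.
oracle_overlap_fraction <- function(query, regions) {
  hit <- vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(regions)), function(j)
      query$chrom[i] == regions$chrom[j] &&
        query$start[i] <= regions$end[j] &&
        regions$start[j] <= query$end[i], TRUE))
  }, TRUE)
  mean(hit)
}

# Brute-force site counter: occurrences of motif on both strands of a DNA
# character string, overlapping occurrences included, N never matches.
oracle_count_sites <- function(seq, motif) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  count_fwd <- function(s, m) {
    k <- nchar(m); n <- nchar(s)
    if (n < k) return(0L)
    sum(vapply(1:(n - k + 1), function(i)
      substr(s, i, i + k - 1) == m, TRUE))
  }
  count_fwd(seq, motif) + count_fwd(seq, revcomp(motif))
}

# Exhaustive k-mer consensus counter: occurrences of an IUPAC consensus in
# each RNA sequence by scanning every k-mer position-wise.
oracle_consensus_counts <- function(seqs, consensus) {
  expand <- c(A = "A", C = "C", G = "G", U = "U",
              M = "AC", R = "AG", W = "AU", S = "CG", Y = "CU", K = "GU")
  cc <- strsplit(consensus, "")[[1]]
  k <- length(cc)
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(0L)
    sum(vapply(1:(n - k + 1), function(i) {
      km <- strsplit(substr(s, i, i + k - 1), "")[[1]]
      all(vapply(seq_len(k), function(j)
        grepl(km[j], expand[[cc[j]]], fixed = TRUE), TRUE))
    }, TRUE))
  }, 0L)
}

# Gene-model helpers shared across tests -------------------------------

# Build a one-or-more-gene GRanges from the plain list description used by
# oracle_label_at.
genes_from_list <- function(genes, sizes = NULL) {
  GeneModels(
    gene_id = vapply(seq_along(genes), function(i)
      paste0("g", i), ""),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0, "tx_start"),
    end = vapply(genes, `[[`, 0, "tx_end"),
    strand = vapply(genes, `[[`, "", "strand"),
    exons = lapply(genes, function(g)
      IRanges::IRanges(vapply(g$exons, `[`, 0, 1),
                       vapply(g$exons, `[`, 0, 2))),
    cds_start = vapply(genes, function(g) as.integer(g$cds_start), 0L),
    cds_end = vapply(genes, function(g) as.integer(g$cds_end), 0L),
    seqinfo = sizes)
}

toy_sizes <- function(...) {
  lens <- c(...)
  GenomeInfoDb::Seqinfo(seqnames = names(lens),
                        seqlengths = as.integer(lens))
}

peaks_gr <- function(chrom, start, end, fdr = 0.01, sizes = NULL) {
  gr <- GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(sizes)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(sizes)
    GenomeInfoDb::seqinfo(gr) <- sizes
  }
  mcols(gr)$name <- paste0("p", seq_along(gr))
  mcols(gr)$score <- 1
  mcols(gr)$fdr <- rep_len(fdr, length(gr))
  gr
}
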