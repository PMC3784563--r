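## Matched-control sampling, miRNA seed-match site prediction, per-miRNA
## enrichment calls, and k-mer consensus motif analysis.

#' Read miRNA sequences
#'
#' Reads a FASTA of mature miRNA sequences (RNA alphabet). Sequences
#' containing `T` are converted to `U` with a warning.
#'
#' @param path FASTA file.
#' @return An `RNAStringSet`.
#' @export
readMiRNAs <- function(path) {
  raw <- readBStringSet(path)
  txt <- toupper(as.character(raw))
  if (any(grepl("T", txt, fixed = TRUE))) {
    warning("miRNA sequences contain T; converting to U")
    txt <- gsub("T", "U", txt, fixed = TRUE)
  }
  ss <- RNAStringSet(txt)
  names(ss) <- names(raw)
  ss
}

#' DNA match motif for a miRNA seed
#'
#' Derives the DNA sequence whose presence in a target constitutes a
#' seed-match site: the reverse complement (in DNA alphabet) of the
#' miRNA's 5' seed under the chosen rule. Rules: `"6mer"` uses miRNA
#' positions 2-7; `"7mer-m8"` (default) positions 2-8; `"8mer"` positions
#' 2-8 plus an `A` opposite position 1 (appended at the 3' end of the
#' site, the canonical 8mer site layout).
#'
#' @param mirna An `RNAString`/`RNAStringSet` element or character
#'   (5' to 3').
#' @param rule Seed rule.
#' @return A `DNAString` match motif (5' to 3').
#' @export
#' @examples
#' seedMatchMotif("UAGCUUAUCAGACUGAUGUUGA")  # ATAAGCT
seedMatchMotif <- function(mirna, rule = c("7mer-m8", "6mer", "8mer")) {
  rule <- match.arg(rule)
  seq <- toupper(as.character(mirna))
  if (nchar(seq) < 8L) stop("miRNA sequence must be at least 8 nt")
  if (!grepl("^[ACGU]+$", seq))
    stop("miRNA sequence must use the RNA alphabet (ACGU)")
  dna <- DNAString(chartr("U", "T", seq))
  core <- reverseComplement(subseq(dna, 2L,
                                   if (rule == "6mer") 7L else 8L))
  if (rule == "8mer") Biostrings::xscat(core, DNAString("A")) else core
}

#' Count miRNA seed-match sites in DNA sequences
#'
#' Counts occurrences of the seed-match motif on both strands of each DNA
#' sequence (the motif and its reverse complement on the forward text).
#' Overlapping occurrences all count; `N` bases never match. Sequences
#' shorter than the motif contribute zero.
#'
#' @param sequences A `DNAStringSet` (or single `DNAString`/character).
#' @param mirna miRNA sequence (see [seedMatchMotif()]).
#' @param rule Seed rule.
#' @return Integer vector of per-sequence site counts.
#' @export
predictTargetSites <- function(sequences, mirna,
                               rule = c("7mer-m8", "6mer", "8mer")) {
  rule <- match.arg(rule)
  if (!is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(sequences)
  motif <- seedMatchMotif(mirna, rule)
  vcountPattern(motif, sequences, fixed = TRUE) +
    vcountPattern(reverseComplement(motif), sequences, fixed = TRUE)
}

#' Sample length- and chromosome-matched control regions
#'
#' Draws, for each peak, one random control interval of identical length on
#' the same chromosome, uniformly positioned, overlapping none of the
#' excluded intervals (by default the peaks themselves). Optionally the
#' control's GC content is matched to its peak within a tolerance by
#' rejection sampling (requires the genome sequence). Fully determined by
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param peaks Peak `GRanges`.
#' @param sizes `Seqinfo` of chromosome lengths.
#' @param seed Integer RNG seed.
#' @param excluded `GRanges` controls must not overlap (default `peaks`).
#' @param gc_tol Optional GC tolerance (fraction, e.g. 0.05) for GC
#'   matching; `NULL` (default) disables it.
#' @param genome `DNAStringSet` named by chromosome; required when
#'   `gc_tol` is set.
#' @param max_attempts Rejection-sampling budget per peak.
#' @return A `GRanges` of control intervals, parallel to `peaks`.
#' @export
sampleMatchedControls <- function(peaks, sizes, seed, excluded = peaks,
                                  gc_tol = NULL, genome = NULL,
                                  max_attempts = 1000L) {
  if (!is.null(gc_tol) && is.null(genome))
    stop("GC matching requires the genome sequence")
  lens <- seqlengths(sizes)
  withSeed(seed, {
    exc <- split(ranges(excluded), as.character(seqnames(excluded)))
    starts <- integer(length(peaks))
    for (i in seq_along(peaks)) {
      ch <- as.character(seqnames(peaks))[i]
      w <- width(peaks)[i]
      L <- lens[[ch]]
      if (is.na(L) || L < w)
        stop("chromosome too short to place a control for peak ", i)
      target_gc <- if (!is.null(gc_tol))
        .gcFraction(subseq(genome[[ch]], start(peaks)[i], end(peaks)[i]))
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        s <- sample.int(L - w + 1L, 1L)
        cand <- IRanges(s, s + w - 1L)
        if (!is.null(exc[[ch]]) && overlapsAny(cand, exc[[ch]])) next
        if (!is.null(gc_tol)) {
          gc <- .gcFraction(subseq(genome[[ch]], s, s + w - 1L))
          if (abs(gc - target_gc) > gc_tol) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop("failed to place a control for peak ", i, " after ",
             max_attempts, " attempts")
      starts[i] <- s
    }
    ctrl <- GRanges(seqnames(peaks), IRanges(starts, width = width(peaks)))
    names(ctrl) <- paste0("control_", seq_along(ctrl))
    ctrl
  })
}

.gcFraction <- function(x)
  sum(letterFrequency(x, c("G", "C"))) / length(x)

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Per-miRNA target-site enrichment in peaks vs matched controls
#'
#' Counts seed-match sites for every miRNA in the peak sequences and the
#' length-matched control sequences, tests the peak/control allocation of
#' sites against Binomial(total, 1/2) (equal total sequence length by
#' construction), adjusts across miRNAs with Benjamini-Hochberg, and calls
#' each miRNA `enriched` (ratio >= `fold_cutoff` and adjusted p < `alpha`),
#' `depleted` (ratio <= 1 / `fold_cutoff`, adjusted p < `alpha`) or
#' `neutral`.
#'
#' @param peak_seqs,control_seqs `DNAStringSet`s of equal element count and
#'   pairwise-matched lengths.
#' @param mirnas `RNAStringSet` of miRNA sequences.
#' @param rule Seed rule (see [seedMatchMotif()]).
#' @param fold_cutoff Enrichment/depletion fold cutoff (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return data.frame with one row per miRNA: `mirna_id`, `sites_peaks`,
#'   `sites_controls`, `ratio` (`Inf` when controls have no sites but
#'   peaks do, `NA` when both are zero), `p_value`, `adj_p`, `call`.
#' @export
mirnaEnrichmentTable <- function(peak_seqs, control_seqs, mirnas,
                                 rule = c("7mer-m8", "6mer", "8mer"),
                                 fold_cutoff = 1.5, alpha = 0.05) {
  rule <- match.arg(rule)
  if (length(peak_seqs) != length(control_seqs) ||
      !all(width(peak_seqs) == width(control_seqs)))
    stop("peak and control sequence sets must be length-matched pairwise")
  motifs <- DNAStringSet(lapply(seq_along(mirnas), function(i)
    seedMatchMotif(mirnas[[i]], rule)))
  rc <- reverseComplement(motifs)
  countAll <- function(seqs)
    vapply(seq_along(motifs), function(i)
      sum(vcountPattern(motifs[[i]], seqs)) +
        sum(vcountPattern(rc[[i]], seqs)), 0)
  sp <- countAll(peak_seqs)
  sc <- countAll(control_seqs)
  tot <- sp + sc
  p <- vapply(seq_along(tot), function(i) {
    if (tot[i] == 0L) return(1)
    binom.test(sp[i], tot[i], 0.5, alternative = "two.sided")$p.value
  }, 0)
  adj <- p.adjust(p, method = "BH")
  ratio <- ifelse(sc > 0, sp / sc, ifelse(sp > 0, Inf, NA_real_))
  call <- rep("neutral", length(tot))
  call[!is.na(ratio) & ratio >= fold_cutoff & adj < alpha] <- "enriched"
  call[!is.na(ratio) & ratio <= 1 / fold_cutoff & adj < alpha] <- "depleted"
  ids <- if (!is.null(names(mirnas))) names(mirnas)
         else paste0("mirna_", seq_along(mirnas))
  data.frame(mirna_id = ids, sites_peaks = as.integer(sp),
             sites_controls = as.integer(sc), ratio = ratio,
             p_value = p, adj_p = adj, call = call, row.names = NULL)
}

## ---- motif discovery ----

# IUPAC code for a pair of RNA bases (sorted).
.IUPAC_PAIR <- c(AC = "M", AG = "R", AU = "W", CG = "S", CU = "Y",
                 GU = "K")

#' Discover a shared k-mer consensus motif across miRNA sequences
#'
#' Enumerates every k-mer of every sequence, merges k-mer pairs differing
#' at exactly one position into IUPAC-degenerate consensi (at most
#' `max_degenerate` degenerate positions), and returns the consensus
#' present in the largest number of sequences. Ties are broken by total
#' occurrence count, then lexicographically.
#'
#' @param mirnas `RNAStringSet` (or character vector) of sequences.
#' @param k Motif length (default 6, minimum 4).
#' @param max_degenerate Maximum degenerate positions (0 or 1; default 1).
#' @return list of class `"MotifResult"`: `consensus` (IUPAC string),
#'   `n_containing`, `n_with_two` (sequences with >= 2 occurrences),
#'   `total_occurrences`.
#' @export
discoverMotif <- function(mirnas, k = 6, max_degenerate = 1) {
  seqs <- toupper(as.character(mirnas))
  if (length(seqs) == 0L) stop("empty input")
  if (k < 4) stop("k must be >= 4")
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }
  per_seq <- lapply(seqs, kmers_of)
  all_kmers <- sort(unique(unlist(per_seq)))
  if (length(all_kmers) == 0L) stop("no k-mers of length ", k)
  # per-sequence occurrence counts of every exact k-mer
  occ <- vapply(per_seq, function(km)
    as.numeric(table(factor(km, levels = all_kmers))),
    numeric(length(all_kmers)))
  occ <- matrix(occ, nrow = length(all_kmers),
                dimnames = list(all_kmers, NULL))
  # candidates: every exact k-mer, plus every IUPAC merge of a k-mer pair
  # differing at exactly one position. A single-degenerate consensus
  # matches exactly its two member k-mers, so its counts are their sums.
  cand_names <- all_kmers
  cand_rows <- lapply(seq_along(all_kmers), function(i) occ[i, ])
  if (max_degenerate >= 1 && length(all_kmers) > 1L) {
    split_kmers <- strsplit(all_kmers, "")
    seen <- character()
    for (i in seq_len(length(all_kmers) - 1L)) {
      a <- split_kmers[[i]]
      for (j in (i + 1L):length(all_kmers)) {
        b <- split_kmers[[j]]
        diff <- which(a != b)
        if (length(diff) != 1L) next
        pair <- paste0(sort(c(a[diff], b[diff])), collapse = "")
        cons <- a
        cons[diff] <- .IUPAC_PAIR[[pair]]
        cons <- paste0(cons, collapse = "")
        if (cons %in% seen) next
        seen <- c(seen, cons)
        cand_names <- c(cand_names, cons)
        cand_rows <- c(cand_rows, list(occ[i, ] + occ[j, ]))
      }
    }
  }
  best <- NULL
  for (ci in seq_along(cand_names)) {
    row <- cand_rows[[ci]]
    stat <- list(consensus = cand_names[ci],
                 n_containing = sum(row >= 1),
                 n_with_two = sum(row >= 2),
                 total_occurrences = sum(row))
    if (is.null(best) ||
        stat$n_containing > best$n_containing ||
        (stat$n_containing == best$n_containing &&
         stat$total_occurrences > best$total_occurrences) ||
        (stat$n_containing == best$n_containing &&
         stat$total_occurrences == best$total_occurrences &&
         stat$consensus < best$consensus))
      best <- stat
  }
  structure(best, class = "MotifResult")
}

#' @export
print.MotifResult <- function(x, ...) {
  cat("Motif consensus ", x$consensus, ": present in ", x$n_containing,
      " sequence(s), ", x$n_with_two, " with two or more occurrences, ",
      x$total_occurrences, " occurrences in total\n", sep = "")
  invisible(x)
}

#' Percent identity between motif variants and a reference
#'
#' Ungapped position-wise identity of each equal-length variant against the
#' reference; the maximum over variants is returned (as matches / length
#' x 100).
#'
#' @param variants Character vector of motif strings.
#' @param reference Reference string of the same length.
#' @return Numeric percent identity (the maximum over variants).
#' @export
#' @examples
#' motifHomology(c("AGUGCU", "AGUGCA"), "AGUGUU")  # 83.33
motifHomology <- function(variants, reference) {
  if (any(nchar(variants) != nchar(reference)))
    stop("variants and reference must have identical length")
  rc <- strsplit(reference, "")[[1L]]
  ident <- vapply(variants, function(v) {
    vc <- strsplit(v, "")[[1L]]
    100 * sum(vc == rc) / length(rc)
  }, 0)
  max(ident)
}

#' Extract interval sequences from a genome
#'
#' @param genome `DNAStringSet` named by chromosome.
#' @param gr `GRanges` of intervals (strand ignored; peak calls are
#'   unstranded).
#' @return `DNAStringSet` of the interval sequences, named after `gr`.
#' @export
extractSequences <- function(genome, gr) {
  chroms <- as.character(seqnames(gr))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("no sequence for chromosome: ", paste(missing, collapse = ", "))
  out <- DNAStringSet(lapply(seq_along(gr), function(i)
    subseq(genome[[chroms[i]]], start(gr)[i], end(gr)[i])))
  names(out) <- if (!is.null(names(gr))) names(gr)
                else if (!is.null(mcols(gr)$name)) mcols(gr)$name
                else paste0("region_", seq_along(gr))
  out
}
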