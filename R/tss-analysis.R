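## Peak distribution relative to TSSs and co-occurrence with an active
## chromatin mark (H3K4me3-style peak set).

# Signed distance from each peak midpoint to its nearest TSS, in gene
# orientation. Nearest by absolute distance; ties broken toward the
# downstream (positive) side, then by gene order. Returns a data.frame
# (peak index, gene index, distance); peaks on chromosomes without genes
# get NA.
nearestTssDistances <- function(peaks, genes) {
  mid <- (start(peaks) - 1L + end(peaks)) %/% 2L + 1L
  pchrom <- as.character(seqnames(peaks))
  gchrom <- as.character(seqnames(genes))
  tss <- ifelse(as.character(strand(genes)) == "+",
                start(genes), end(genes))
  gsgn <- ifelse(as.character(strand(genes)) == "+", 1L, -1L)
  out_gene <- rep(NA_integer_, length(peaks))
  out_dist <- rep(NA_integer_, length(peaks))
  for (ch in unique(pchrom)) {
    gi <- which(gchrom == ch)
    if (length(gi) == 0L) next
    pi <- which(pchrom == ch)
    ord <- order(tss[gi], gi)
    gi <- gi[ord]
    st <- tss[gi]
    idx <- findInterval(mid[pi], st)
    for (k in seq_along(pi)) {
      p <- mid[pi[k]]
      cand <- unique(pmax(1L, pmin(length(gi), c(idx[k], idx[k] + 1L))))
      # widen to catch all ties at the minimal absolute distance
      d_abs <- abs(p - st[cand])
      dmin <- min(d_abs)
      cand <- which(abs(p - st) == dmin)
      signed <- (p - st[cand]) * gsgn[gi[cand]]
      pick <- order(-sign(signed), gi[cand])[1L]
      out_gene[pi[k]] <- gi[cand[pick]]
      out_dist[pi[k]] <- signed[pick]
    }
  }
  data.frame(peak = seq_along(peaks), gene = out_gene, distance = out_dist)
}

#' Histogram of peak distances to the nearest TSS
#'
#' Assigns each peak the signed, strand-oriented distance from its midpoint
#' to the nearest TSS, keeps peaks with `|distance| <= window`, and bins
#' the distances. Bins are `[k * bin_width, (k + 1) * bin_width)`; the
#' single distance equal to `+window` is placed in the last bin.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene-model `GRanges` (must be non-empty).
#' @param window Half-window in bp (default 5000).
#' @param bin_width Bin width in bp; must divide `2 * window`.
#' @return A list of class `"TSSHistogram"`: `breaks` (bin start offsets),
#'   `counts`, `n_peaks_in_window`, `window`, `bin_width`.
#' @export
tssDistanceHistogram <- function(peaks, genes, window = 5000,
                                 bin_width = 100) {
  if (length(genes) == 0L) stop("no genes supplied")
  if (window <= 0) stop("window must be positive")
  if ((2 * window) %% bin_width != 0)
    stop("bin_width must divide 2 * window")
  d <- nearestTssDistances(peaks, genes)$distance
  d <- d[!is.na(d) & abs(d) <= window]
  breaks <- seq(-window, window - bin_width, by = bin_width)
  bin <- pmin(floor(d / bin_width) * bin_width, window - bin_width)
  counts <- table(factor(bin, levels = breaks))
  structure(list(breaks = breaks,
                 counts = setNames(as.integer(counts), breaks),
                 n_peaks_in_window = length(d),
                 window = window, bin_width = bin_width),
            class = "TSSHistogram")
}

#' @export
print.TSSHistogram <- function(x, ...) {
  cat("TSS distance histogram: ", x$n_peaks_in_window,
      " peaks within ±", x$window, " bp (bin ", x$bin_width,
      " bp)\n", sep = "")
  invisible(x)
}

#' Co-occurrence of TSS-proximal peaks with a chromatin mark
#'
#' Among query peaks whose midpoint lies within `window` bp of the nearest
#' TSS, the fraction that overlap (share at least 1 bp with) any mark peak.
#'
#' @param peaks Query peak `GRanges`.
#' @param mark_peaks Mark (e.g. H3K4me3) peak `GRanges`.
#' @param genes Gene-model `GRanges`.
#' @param window TSS proximity half-window in bp (default 1000).
#' @return list with `fraction` (`NA` when no peak is TSS-proximal),
#'   `numerator` and `denominator`.
#' @export
tssMarkOverlap <- function(peaks, mark_peaks, genes, window = 1000) {
  d <- nearestTssDistances(peaks, genes)$distance
  prox <- !is.na(d) & abs(d) <= window
  denom <- sum(prox)
  if (denom == 0L)
    return(list(fraction = NA_real_, numerator = 0L, denominator = 0L))
  hit <- overlapsAny(peaks[prox], mark_peaks, ignore.strand = TRUE)
  list(fraction = sum(hit) / denom, numerator = sum(hit),
       denominator = denom)
}
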