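## Peak I/O, validation-driven FDR cutoff selection, filtering and
## descriptive statistics.

#' Read scored peaks with per-peak FDR
#'
#' Reads a BED6+1 peak file as emitted by a control-based peak caller:
#' the six standard BED columns plus a seventh column holding the caller's
#' per-peak FDR (a fraction in [0, 1]). BED coordinates (0-based
#' half-open) are converted to the internal 1-based closed convention.
#'
#' @param path Peak file.
#' @param seqinfo Optional `Seqinfo` for bounds checking.
#' @return A `GRanges` with metadata columns `name`, `score` and `fdr`.
#' @export
readPeaks <- function(path, seqinfo = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  empty <- GRanges(seqinfo = seqinfo)
  mcols(empty) <- DataFrame(name = character(), score = numeric(),
                            fdr = numeric())
  if (length(lines) == 0L) return(empty)
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(fdr = "numeric"))
  bad <- is.na(mcols(gr)$fdr) | mcols(gr)$fdr < 0 | mcols(gr)$fdr > 1
  if (any(bad))
    stop("invalid FDR outside [0, 1] at line ", which(bad)[1L],
         " of '", path, "'")
  if (!is.null(seqinfo)) {
    seqlevels(gr) <- seqlevels(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  mcols(gr) <- mcols(gr)[c("name", "score", "fdr")]
  gr
}

#' Write peaks as BED6+1
#'
#' @param peaks Peak `GRanges` with `name`, `score`, `fdr` metadata.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  lines <- paste(as.character(seqnames(peaks)), start(peaks) - 1L,
                 end(peaks),
                 if (!is.null(mcols(peaks)$name)) mcols(peaks)$name
                 else paste0("peak_", seq_along(peaks)),
                 if (!is.null(mcols(peaks)$score)) mcols(peaks)$score else 0,
                 ".", mcols(peaks)$fdr, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ChIP-qPCR validation table
#'
#' Tab-separated with header columns `fdr_lo`, `fdr_hi`, `n_tested`,
#' `n_validated`: for each FDR range of called peaks, how many randomly
#' selected peaks were tested by independent ChIP-qPCR and how many
#' validated.
#'
#' @param path Validation table file.
#' @return data.frame with an additional `rate` column.
#' @export
readValidationBins <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("fdr_lo", "fdr_hi", "n_tested", "n_validated")
  if (!all(need %in% names(tab)))
    stop("validation table must have columns: ",
         paste(need, collapse = ", "))
  if (any(tab$n_validated > tab$n_tested) || any(tab$n_tested <= 0))
    stop("need 0 <= n_validated <= n_tested and n_tested > 0")
  tab$rate <- tab$n_validated / tab$n_tested
  tab
}

#' Select an FDR cutoff from validation rates
#'
#' Scans validation bins in increasing FDR order and returns the upper FDR
#' bound of the last bin in the maximal prefix of bins whose validation
#' rates are all at least `min_rate`. This formalizes choosing the most
#' permissive cutoff that independent ChIP validation still supports. When
#' even the first bin fails, `NA` is returned (no defensible cutoff).
#'
#' @param bins data.frame as returned by [readValidationBins()] (columns
#'   `fdr_lo`, `fdr_hi`, `n_tested`, `n_validated`; `rate` recomputed).
#' @param min_rate Minimum acceptable validation rate, in (0, 1].
#' @return The cutoff (numeric scalar) or `NA_real_`.
#' @export
#' @examples
#' bins <- data.frame(fdr_lo = c(0, 0.02, 0.054),
#'                    fdr_hi = c(0.02, 0.054, 0.1),
#'                    n_tested = c(10, 10, 10),
#'                    n_validated = c(10, 9, 5))
#' selectFdrCutoff(bins, min_rate = 0.8)  # 0.054
selectFdrCutoff <- function(bins, min_rate) {
  if (nrow(bins) < 1L) stop("need at least one validation bin")
  if (min_rate <= 0 || min_rate > 1) stop("min_rate must lie in (0, 1]")
  if (any(bins$fdr_lo >= bins$fdr_hi))
    stop("each bin needs fdr_lo < fdr_hi")
  if (is.unsorted(bins$fdr_lo) ||
      (nrow(bins) > 1L && any(bins$fdr_lo[-1L] < bins$fdr_hi[-nrow(bins)])))
    stop("validation bins must be sorted and non-overlapping")
  rate <- bins$n_validated / bins$n_tested
  pass <- rate >= min_rate
  k <- if (all(pass)) nrow(bins) else which(!pass)[1L] - 1L
  if (k == 0L) NA_real_ else bins$fdr_hi[k]
}

#' Filter peaks at an FDR cutoff
#'
#' Retains peaks with `fdr <= cutoff` (inclusive), preserving order.
#'
#' @param peaks Peak `GRanges` with an `fdr` metadata column.
#' @param cutoff FDR cutoff in [0, 1].
#' @return The retained peaks.
#' @export
filterPeaks <- function(peaks, cutoff) {
  if (is.na(cutoff) || cutoff < 0 || cutoff > 1)
    stop("cutoff must lie in [0, 1]")
  peaks[mcols(peaks)$fdr <= cutoff]
}

#' Descriptive peak statistics
#'
#' Peak count, size quantiles, per-chromosome density (peaks per `window`
#' bp) and mean genomic spacing (total genome bp per peak, reported in kb).
#'
#' @param peaks Peak `GRanges`.
#' @param sizes `Seqinfo` of chromosome lengths.
#' @param window Density window in bp (default 1e5, i.e. peaks/100 kb).
#' @return A list with elements `n_peaks`, `size_quantiles`, `density`
#'   (data.frame chrom, length, n_peaks, density) and `spacing_kb`
#'   (`NA` when there are no peaks).
#' @export
summarizePeaks <- function(peaks, sizes, window = 1e5) {
  chroms <- seqnames(sizes)
  if (length(peaks) &&
      !all(as.character(seqnames(peaks)) %in% chroms))
    stop("peak on unknown chromosome")
  lens <- as.numeric(seqlengths(sizes))
  cnt <- table(factor(as.character(seqnames(peaks)), levels = chroms))
  density <- data.frame(chrom = chroms, length = lens,
                        n_peaks = as.integer(cnt),
                        density = as.integer(cnt) / lens * window,
                        row.names = NULL)
  n <- length(peaks)
  list(n_peaks = n,
       size_quantiles = if (n) quantile(width(peaks)) else NULL,
       density = density,
       spacing_kb = if (n) sum(lens) / n / 1000 else NA_real_)
}
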