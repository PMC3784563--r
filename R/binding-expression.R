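## Bound-gene and responsive-gene set construction, hypergeometric overlap
## testing, and the 1-bp positional enrichment scan around TSSs.

#' Read a differential-expression table
#'
#' Tab-separated with header. The fold-change dialect is declared by the
#' column name, never guessed from the values: a `fold_change` column holds
#' linear ratios (knockdown vs control, > 0), a `log2_fold_change` column
#' holds log2 ratios. A `p_value` column is required. Both fold-change
#' representations are returned.
#'
#' @param path Expression table file.
#' @return data.frame with columns `gene_id`, `fold_change`,
#'   `log2_fold_change`, `p_value`.
#' @export
readExpressionTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("expression table needs gene_id")
  if (!"p_value" %in% names(tab)) stop("expression table needs p_value")
  if ("fold_change" %in% names(tab)) {
    if (any(tab$fold_change <= 0))
      stop("linear fold changes must be positive")
    tab$log2_fold_change <- log2(tab$fold_change)
  } else if ("log2_fold_change" %in% names(tab)) {
    tab$fold_change <- 2^tab$log2_fold_change
  } else {
    stop("expression table must declare its dialect with a fold_change ",
         "or log2_fold_change column")
  }
  if (any(tab$p_value < 0 | tab$p_value > 1))
    stop("p_value outside [0, 1]")
  tab[c("gene_id", "fold_change", "log2_fold_change", "p_value")]
}

#' Genes bound near their TSS
#'
#' For each window W, the set of genes with at least one peak midpoint at
#' absolute signed TSS distance <= W from the gene's own TSS. Sets are
#' nested by construction: smaller windows give subsets.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene-model `GRanges`.
#' @param windows Numeric vector of half-windows in bp
#'   (default `c(5000, 1000, 500)`).
#' @return Named list (one element per window, e.g. `"5000"`) of gene-id
#'   character vectors.
#' @export
boundGenes <- function(peaks, genes, windows = c(5000, 1000, 500)) {
  if (any(windows <= 0)) stop("windows must be positive")
  minAbs <- .minAbsTssDistance(peaks, genes)
  out <- lapply(windows, function(W)
    mcols(genes)$gene_id[!is.na(minAbs) & minAbs <= W])
  names(out) <- as.character(windows)
  out
}

# Per gene, the minimal |signed TSS distance| over all peak midpoints on
# the same chromosome (NA when the chromosome has no peaks).
.minAbsTssDistance <- function(peaks, genes) {
  mid <- (start(peaks) - 1L + end(peaks)) %/% 2L + 1L
  pchrom <- as.character(seqnames(peaks))
  gchrom <- as.character(seqnames(genes))
  tss <- ifelse(as.character(strand(genes)) == "+",
                start(genes), end(genes))
  out <- rep(NA_integer_, length(genes))
  for (ch in unique(gchrom)) {
    pm <- sort(mid[pchrom == ch])
    if (length(pm) == 0L) next
    gi <- which(gchrom == ch)
    idx <- findInterval(tss[gi], pm)
    lo <- pmax(1L, idx); hi <- pmin(length(pm), idx + 1L)
    out[gi] <- pmin(abs(tss[gi] - pm[lo]), abs(tss[gi] - pm[hi]))
  }
  out
}

#' Responsive genes from an expression table
#'
#' Splits genes into up- and downregulated sets with strict thresholds:
#' up when `fold_change > fc_threshold` and `p_value < p_threshold`, down
#' when `fold_change < 1 / fc_threshold` and `p_value < p_threshold`.
#' A fold change exactly at the threshold is excluded.
#'
#' @param expr data.frame as returned by [readExpressionTable()].
#' @param fc_threshold Linear fold-change threshold (default 1.2).
#' @param p_threshold P-value threshold (default 0.05).
#' @param collapse When `TRUE`, duplicate gene ids are collapsed to the
#'   record with the largest absolute log2 fold change; otherwise
#'   duplicates are an error.
#' @return list with character vectors `up` and `down`.
#' @export
responsiveGenes <- function(expr, fc_threshold = 1.2, p_threshold = 0.05,
                            collapse = FALSE) {
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  if (anyDuplicated(expr$gene_id)) {
    if (!collapse)
      stop("duplicate gene ids in expression table ",
           "(set collapse = TRUE to keep the largest |log2FC|)")
    ord <- order(-abs(expr$log2_fold_change))
    expr <- expr[ord, ]
    expr <- expr[!duplicated(expr$gene_id), ]
  }
  sig <- expr$p_value < p_threshold
  list(up = expr$gene_id[sig & expr$fold_change > fc_threshold],
       down = expr$gene_id[sig & expr$fold_change < 1 / fc_threshold])
}

#' Hypergeometric gene-set overlap test
#'
#' Tests whether the observed overlap between two gene sets drawn from a
#' common universe is larger than expected by chance: exact hypergeometric
#' upper-tail probability of observing at least `k` shared genes.
#'
#' @param setA,setB Character vectors of gene ids; both must be subsets of
#'   `universe`.
#' @param universe Character vector, the gene universe.
#' @return list with `N`, `nA`, `nB`, `k`, `expected` (`nA * nB / N`) and
#'   `p_value`.
#' @export
overlapTest <- function(setA, setB, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("empty universe")
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  nA <- length(setA); nB <- length(setB)
  k <- length(intersect(setA, setB))
  p <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  list(N = N, nA = nA, nB = nB, k = k, expected = nA * nB / N,
       p_value = p)
}

#' 1-bp positional scan of binding-responsiveness enrichment
#'
#' For every offset d in `[-window, +window]` (1-bp steps, gene-oriented),
#' the genes bound at d are those with at least one peak interval covering
#' the base TSS + d. The scan reports, per offset and per direction, the
#' hypergeometric upper-tail p-value for enrichment of the responsive set
#' among the bound genes relative to the universe. Offsets where no gene
#' is bound have p = 1 by convention. Raw per-offset p-values are
#' reported (neighbouring offsets are strongly dependent, so curve-wise
#' multiplicity correction is left to the caller).
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene-model `GRanges`; only genes whose id is in `universe`
#'   participate.
#' @param up,down Character vectors of responsive gene ids (intersected
#'   with the universe).
#' @param universe Character vector of gene ids (typically genes present
#'   in both the annotation and the expression table).
#' @param window Scan half-width in bp (default 5000).
#' @return A [PositionalScanResult-class].
#' @export
positionalScan <- function(peaks, genes, up, down, universe,
                           window = 5000) {
  if (length(universe) == 0L) stop("empty universe")
  if (window < 1) stop("window must be >= 1")
  W <- as.integer(window)
  universe <- unique(universe)
  genes <- genes[mcols(genes)$gene_id %in% universe]
  up <- intersect(unique(up), universe)
  down <- intersect(unique(down), universe)
  L <- 2L * W + 1L
  incAll <- numeric(L + 1L)
  incUp <- numeric(L + 1L)
  incDown <- numeric(L + 1L)
  tss <- ifelse(as.character(strand(genes)) == "+",
                start(genes), end(genes))
  gplus <- as.character(strand(genes)) == "+"
  win <- GRanges(seqnames(genes),
                 IRanges(pmax(1L, tss - W), tss + W))
  hits <- findOverlaps(win, peaks, ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  for (g in unique(qh)) {
    pk <- sh[qh == g]
    if (gplus[g]) {
      a <- start(peaks)[pk] - tss[g]; b <- end(peaks)[pk] - tss[g]
    } else {
      a <- tss[g] - end(peaks)[pk]; b <- tss[g] - start(peaks)[pk]
    }
    a <- pmax(a, -W); b <- pmin(b, W)
    keep <- a <= b
    if (!any(keep)) next
    iv <- reduce(IRanges(a[keep] + W + 1L, b[keep] + W + 1L))
    id <- mcols(genes)$gene_id[g]
    for (j in seq_along(iv)) {
      i1 <- start(iv)[j]; i2 <- end(iv)[j]
      incAll[i1] <- incAll[i1] + 1; incAll[i2 + 1L] <- incAll[i2 + 1L] - 1
      if (id %in% up) {
        incUp[i1] <- incUp[i1] + 1; incUp[i2 + 1L] <- incUp[i2 + 1L] - 1
      }
      if (id %in% down) {
        incDown[i1] <- incDown[i1] + 1
        incDown[i2 + 1L] <- incDown[i2 + 1L] - 1
      }
    }
  }
  nBound <- as.integer(cumsum(incAll)[seq_len(L)])
  kUp <- as.integer(cumsum(incUp)[seq_len(L)])
  kDown <- as.integer(cumsum(incDown)[seq_len(L)])
  N <- length(universe)
  pUp <- phyper(kUp - 1, length(up), N - length(up), nBound,
                lower.tail = FALSE)
  pDown <- phyper(kDown - 1, length(down), N - length(down), nBound,
                  lower.tail = FALSE)
  offsets <- (-W):W
  argmin <- function(p) {
    ord <- order(p, abs(offsets), -sign(offsets))
    as.integer(offsets[ord[1L]])
  }
  new("PositionalScanResult", offsets = as.integer(offsets),
      pUp = pUp, pDown = pDown, nBound = nBound, kUp = kUp, kDown = kDown,
      universeSize = as.integer(N), nUp = length(up), nDown = length(down),
      argminUp = argmin(pUp), argminDown = argmin(pDown),
      minPUp = min(pUp), minPDown = min(pDown))
}
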