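## Coordinate model, gene-model I/O, genome partitioning and TSS arithmetic.
## Internal coordinates follow the GRanges convention (1-based, closed);
## BED input/output is converted at the I/O boundary, GTF is 1-based already.

#' Read chromosome sizes
#'
#' Reads a two-column tab-separated file (chromosome name, length in bp)
#' into a [GenomeInfoDb::Seqinfo-class].
#'
#' @param path Path to the chrom.sizes file.
#' @return A `Seqinfo` with one entry per chromosome.
#' @export
readChromSizes <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("chromosome sizes file must have two columns: name, length")
  nm <- as.character(tab[[1L]])
  len <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(len) || any(len <= 0))
    stop("chromosome lengths must be positive integers")
  if (anyDuplicated(nm)) stop("duplicated chromosome names")
  Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Construct validated gene models
#'
#' Builds the gene-model container used throughout the package: a
#' [GenomicRanges::GRanges-class] spanning each transcript, with metadata
#' columns `gene_id`, `cds_start`/`cds_end` (NA when the gene is
#' non-coding) and `exons` (an [IRanges::IRangesList-class] of absolute
#' exon coordinates). All coordinates are 1-based closed.
#'
#' Validation enforces the model invariants: at least one exon per gene,
#' exons sorted, non-overlapping and inside the transcript, CDS bounds
#' inside the transcript, strand either `+` or `-`.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param chrom Chromosome name per gene.
#' @param start,end Transcript bounds (1-based closed).
#' @param strand `"+"` or `"-"` per gene.
#' @param exons List (or `IRangesList`) of exon `IRanges` per gene, in
#'   absolute coordinates.
#' @param cds_start,cds_end CDS bounds, or `NA` for non-coding genes.
#' @param seqinfo Optional `Seqinfo`; when supplied, genes must fit their
#'   chromosomes.
#' @return A `GRanges` of gene models.
#' @export
#' @examples
#' g <- GeneModels("g1", "chr1", 1000, 2000, "+",
#'                 list(IRanges::IRanges(c(1000, 1800), c(1200, 2000))),
#'                 cds_start = 1100, cds_end = 1900)
#' tssPositions(g)
GeneModels <- function(gene_id, chrom, start, end, strand, exons,
                       cds_start = NA_integer_, cds_end = NA_integer_,
                       seqinfo = NULL) {
  n <- length(gene_id)
  cds_start <- rep_len(as.integer(cds_start), n)
  cds_end <- rep_len(as.integer(cds_end), n)
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)),
                strand = strand)
  if (!is.null(seqinfo)) {
    seqlevels(gr) <- seqlevels(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  mcols(gr)$gene_id <- as.character(gene_id)
  mcols(gr)$cds_start <- cds_start
  mcols(gr)$cds_end <- cds_end
  mcols(gr)$exons <- as(exons, "IRangesList")
  validateGeneModels(gr)
  gr
}

#' @rdname GeneModels
#' @param genes A gene-model `GRanges` to validate.
#' @export
validateGeneModels <- function(genes) {
  mc <- mcols(genes)
  ex <- mc$exons
  ids <- mc$gene_id
  gs <- start(genes); ge <- end(genes)
  es <- start(ex); ee <- end(ex)
  for (i in seq_along(genes)) {
    e_s <- es[[i]]; e_e <- ee[[i]]
    id <- ids[i]
    if (length(e_s) == 0L)
      stop("gene '", id, "': gene models without exons are rejected")
    if (is.unsorted(e_s))
      stop("gene '", id, "': exons must be sorted by start")
    if (length(e_s) > 1L && any(e_s[-1L] <= e_e[-length(e_e)]))
      stop("gene '", id, "': exons must not overlap")
    if (min(e_s) < gs[i] || max(e_e) > ge[i])
      stop("gene '", id, "': exon outside transcript bounds")
    cs <- mc$cds_start[i]; ce <- mc$cds_end[i]
    if (xor(is.na(cs), is.na(ce)))
      stop("gene '", id, "': cds_start and cds_end must both be set or both NA")
    if (!is.na(cs) && (cs > ce || cs < gs[i] || ce > ge[i]))
      stop("gene '", id, "': CDS outside transcript bounds")
  }
  invisible(genes)
}

#' Read gene models from BED12 or GTF
#'
#' Parses a gene annotation into the validated gene-model `GRanges` of
#' [GeneModels()]. BED12 coordinates (0-based half-open) are converted to
#' the internal 1-based closed convention; GTF (1-based closed) is taken
#' as is. The dialect is chosen from the file extension unless `format`
#' is given.
#'
#' @param path Annotation file.
#' @param format `"auto"` (default, by extension), `"bed12"` or `"gtf"`.
#' @param seqinfo Optional `Seqinfo` for bounds checking.
#' @return Gene-model `GRanges` (see [GeneModels()]).
#' @export
readGeneModels <- function(path, format = c("auto", "bed12", "gtf"),
                           seqinfo = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "bed12") .readGeneModelsBed12(path, seqinfo)
  else .readGeneModelsGtf(path, seqinfo)
}

.readGeneModelsBed12 <- function(path, seqinfo = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12L))
    stop("parse error in '", path, "': line ",
         which(nf != 12L)[1L], " does not have 12 tab-separated fields")
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stop("parse error in '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  # rtracklayer returns 1-based closed ranges; blocks are relative to the
  # transcript start, thick is the CDS (zero width when absent).
  exons <- IRangesList(lapply(seq_along(gr), function(i)
    shift(mcols(gr)$blocks[[i]], start(gr)[i] - 1L)))
  thick <- mcols(gr)$thick
  has_cds <- width(thick) > 0L
  GeneModels(gene_id = mcols(gr)$name,
             chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             strand = as.character(strand(gr)),
             exons = exons,
             cds_start = ifelse(has_cds, start(thick), NA_integer_),
             cds_end = ifelse(has_cds, end(thick), NA_integer_),
             seqinfo = seqinfo)
}

.readGeneModelsGtf <- function(path, seqinfo = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("parse error in '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  txid <- mcols(gr)$transcript_id
  if (is.null(txid)) stop("GTF records lack transcript_id attributes")
  is_exon <- mcols(gr)$type == "exon"
  is_cds <- mcols(gr)$type == "CDS"
  ids <- unique(txid[is_exon | is_cds])
  if (length(ids) == 0L) stop("no exon records found in '", path, "'")
  recs <- lapply(ids, function(id) {
    sel <- !is.na(txid) & txid == id
    e <- gr[sel & is_exon]
    if (length(e) == 0L)
      stop("gene '", id, "': gene models without exons are rejected")
    cds <- gr[sel & is_cds]
    gid <- mcols(e)$gene_id[1L]
    if (is.null(gid) || is.na(gid)) gid <- id
    list(gene_id = gid,
         chrom = as.character(seqnames(e))[1L],
         start = min(start(e)), end = max(end(e)),
         strand = as.character(strand(e))[1L],
         exons = IRanges(sort(start(e)), sort(end(e))),
         cds_start = if (length(cds)) min(start(cds)) else NA_integer_,
         cds_end = if (length(cds)) max(end(cds)) else NA_integer_)
  })
  GeneModels(gene_id = vapply(recs, `[[`, "", "gene_id"),
             chrom = vapply(recs, `[[`, "", "chrom"),
             start = vapply(recs, `[[`, 0, "start"),
             end = vapply(recs, `[[`, 0, "end"),
             strand = vapply(recs, `[[`, "", "strand"),
             exons = IRangesList(lapply(recs, `[[`, "exons")),
             cds_start = vapply(recs, `[[`, NA_integer_, "cds_start"),
             cds_end = vapply(recs, `[[`, NA_integer_, "cds_end"),
             seqinfo = seqinfo)
}

#' Write gene models as BED12
#'
#' Inverse of [readGeneModels()] for the BED12 dialect; a read/write
#' round trip reproduces all gene-model fields.
#'
#' @param genes Gene-model `GRanges`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  validateGeneModels(genes)
  ex <- mcols(genes)$exons
  lines <- vapply(seq_along(genes), function(i) {
    e <- ex[[i]]
    s0 <- start(genes)[i] - 1L
    cs <- mcols(genes)$cds_start[i]; ce <- mcols(genes)$cds_end[i]
    thick <- if (is.na(cs)) c(s0, s0) else c(cs - 1L, ce)
    paste(as.character(seqnames(genes))[i], s0, end(genes)[i],
          mcols(genes)$gene_id[i], 0L, as.character(strand(genes))[i],
          thick[1L], thick[2L], 0L, length(e),
          paste0(width(e), collapse = ","),
          paste0(start(e) - 1L - s0, collapse = ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' TSS positions of gene models
#'
#' The transcription start site is the strand-oriented 5' end of the
#' transcript: the transcript start for `+` genes, the transcript end for
#' `-` genes (the last transcribed base in genomic coordinates).
#'
#' @param genes Gene-model `GRanges`.
#' @return Integer vector of 1-based TSS positions named by `gene_id`.
#' @export
tssPositions <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "+",
                start(genes), end(genes))
  names(pos) <- mcols(genes)$gene_id
  pos
}

#' Signed, strand-aware distance from a TSS
#'
#' Distance in gene orientation from the TSS base to `position`: 0 at the
#' TSS, positive downstream (into the gene body), negative upstream.
#'
#' @param genes Gene-model `GRanges` (recycled against `position`).
#' @param position Integer genomic position(s), 1-based.
#' @param chrom Optional chromosome of `position`; when given it must match
#'   the gene's chromosome.
#' @return Integer vector of signed distances.
#' @export
#' @examples
#' g <- GeneModels("g", "chr1", 1001, 2000, "+",
#'                 list(IRanges::IRanges(1001, 2000)))
#' signedTssDistance(g, 1101)  # +100
signedTssDistance <- function(genes, position, chrom = NULL) {
  if (!is.null(chrom) && !all(chrom == as.character(seqnames(genes))))
    stop("position chromosome does not match the gene's chromosome")
  tss <- ifelse(as.character(strand(genes)) == "+",
                start(genes), end(genes))
  ifelse(as.character(strand(genes)) == "+",
         as.integer(position) - tss, tss - as.integer(position))
}

#' Partition a genome into feature classes
#'
#' Labels every base of the genome with exactly one class from
#' [featureClasses()], applying precedence promoter > 5'UTR > coding exon >
#' intron > 3'UTR > 3' flank > intergenic. The promoter is the
#' `flank_width` bp immediately upstream of the TSS (strand-aware); the 3'
#' flank is the `flank_width` bp immediately downstream of the gene end.
#' Genes without CDS annotation contribute all exons as `coding_exon` and
#' no UTR classes.
#'
#' @param genes Gene-model `GRanges` (may be empty: the whole genome is then
#'   intergenic).
#' @param sizes A `Seqinfo` of chromosome lengths.
#' @param flank_width Promoter / 3' flank width in bp (default 5000).
#' @return A [FeatureMap-class].
#' @export
partitionGenome <- function(genes, sizes, flank_width = 5000) {
  if (flank_width <= 0) stop("flank_width must be positive")
  chroms <- seqnames(sizes)
  lens <- seqlengths(sizes)
  if (length(genes) && !all(as.character(seqnames(genes)) %in% chroms))
    stop("gene on unknown chromosome: ",
         setdiff(as.character(seqnames(genes)), chroms)[1L])
  ranges_by_class <- .geneFeatureRanges(genes, flank_width)
  labels <- setNames(vector("list", length(chroms)), chroms)
  comp <- setNames(numeric(7L), .FEATURE_CLASSES)
  for (chrom in chroms) {
    L <- lens[[chrom]]
    v <- rep.int(7L, L)  # 7 = intergenic
    # Apply in increasing precedence so later classes overwrite earlier ones.
    for (code in 6L:1L) {
      rl <- ranges_by_class[[.FEATURE_CLASSES[code]]]
      if (is.null(rl)) next
      rl <- rl[rl$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(rl))) {
        s <- max(1L, as.integer(rl$start[j]))
        e <- min(L, as.integer(rl$end[j]))
        if (s <= e) v[s:e] <- code
      }
    }
    labels[[chrom]] <- Rle(factor(.FEATURE_CLASSES[v],
                                  levels = .FEATURE_CLASSES))
    comp <- comp + tabulate(v, 7L)
  }
  new("FeatureMap", labels = labels, composition = comp,
      flankWidth = flank_width)
}

# Per-class genomic ranges (data.frames chrom/start/end) for one gene set.
.geneFeatureRanges <- function(genes, flank_width) {
  out <- setNames(vector("list", 6L), .FEATURE_CLASSES[1:6])
  add <- function(cls, chrom, s, e) {
    keep <- s <= e
    if (!any(keep)) return()
    out[[cls]] <<- rbind(out[[cls]],
                         data.frame(chrom = chrom[keep], start = s[keep],
                                    end = e[keep]))
  }
  for (i in seq_along(genes)) {
    chrom <- as.character(seqnames(genes))[i]
    st <- as.character(strand(genes))[i]
    s <- start(genes)[i]; e <- end(genes)[i]
    ex <- mcols(genes)$exons[[i]]
    cs <- mcols(genes)$cds_start[i]; ce <- mcols(genes)$cds_end[i]
    if (st == "+") {
      add("promoter", chrom, s - flank_width, s - 1L)
      add("three_prime_flank", chrom, e + 1L, e + flank_width)
    } else {
      add("promoter", chrom, e + 1L, e + flank_width)
      add("three_prime_flank", chrom, s - flank_width, s - 1L)
    }
    # introns: transcript minus exons
    if (length(ex) > 1L)
      add("intron", rep(chrom, length(ex) - 1L),
          head(end(ex), -1L) + 1L, tail(start(ex), -1L) - 1L)
    if (is.na(cs)) {
      add("coding_exon", rep(chrom, length(ex)), start(ex), end(ex))
    } else {
      clip <- function(lo, hi) {
        ss <- pmax(start(ex), lo); ee <- pmin(end(ex), hi)
        keep <- ss <= ee
        list(s = ss[keep], e = ee[keep])
      }
      cd <- clip(cs, ce)
      add("coding_exon", rep(chrom, length(cd$s)), cd$s, cd$e)
      five <- if (st == "+") clip(s, cs - 1L) else clip(ce + 1L, e)
      three <- if (st == "+") clip(ce + 1L, e) else clip(s, cs - 1L)
      add("five_prime_utr", rep(chrom, length(five$s)), five$s, five$e)
      add("three_prime_utr", rep(chrom, length(three$s)), three$s, three$e)
    }
  }
  out
}

#' Locate an interval in a feature map
#'
#' In `"midpoint"` mode returns the single label at the interval midpoint;
#' in `"bp_composition"` mode returns the fraction of interval bases in
#' each class (fractions sum to 1).
#'
#' @param fm A [FeatureMap-class].
#' @param gr A `GRanges` of query intervals (all within known chromosomes).
#' @param mode `"midpoint"` or `"bp_composition"`.
#' @return Character vector of labels (midpoint mode) or a numeric matrix
#'   with one row per interval and one column per class.
#' @export
locateInterval <- function(fm, gr, mode = c("midpoint", "bp_composition")) {
  mode <- match.arg(mode)
  chroms <- as.character(seqnames(gr))
  bad <- !chroms %in% names(fm@labels)
  if (any(bad))
    stop("interval on unknown chromosome: ", chroms[bad][1L])
  lens <- vapply(fm@labels, length, 0L)
  if (any(start(gr) < 1L | end(gr) > lens[chroms]))
    stop("interval outside chromosome bounds")
  if (mode == "midpoint") {
    # midpoint base of [s, e] (1-based closed): floor((s - 1 + e) / 2) + 1,
    # i.e. the 0-based floor((start + end) / 2) convention.
    mid <- (start(gr) - 1L + end(gr)) %/% 2L + 1L
    vapply(seq_along(gr), function(i)
      as.character(fm@labels[[chroms[i]]][mid[i]]), "")
  } else {
    m <- t(vapply(seq_along(gr), function(i) {
      v <- as.character(fm@labels[[chroms[i]]][start(gr)[i]:end(gr)[i]])
      tab <- table(factor(v, levels = .FEATURE_CLASSES))
      as.numeric(tab) / width(gr)[i]
    }, numeric(7L)))
    colnames(m) <- .FEATURE_CLASSES
    rownames(m) <- if (!is.null(names(gr))) names(gr) else NULL
    m
  }
}
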