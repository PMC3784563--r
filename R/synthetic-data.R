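## Seeded synthetic dataset generator: a toy genome with gene models,
## TSS-proximal and background peaks, an active-promoter mark, repeats,
## HOT-style regions, a knockdown expression table coupled to binding, and
## miRNA sequences with target sites implanted into bound sequence.
## Every output draws from its own RNG substream derived from the master
## seed, so adding one output never perturbs the others.

#' Construct a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of every parameter. The
#' defaults describe the emulated study conditions; pass overrides as
#' named arguments.
#'
#' @param seed Master seed (mandatory).
#' @param chromLengths,nGenes,fractionActive,nTssPeaks,nBackgroundPeaks
#'   Genome and peak-placement parameters.
#' @param offsetMean,offsetSd,effectOffset,effectSd TSS-offset model (bp).
#' @param peakWidthMean,peakWidthSd,minPeakWidth Peak width model (bp).
#' @param k4Prob,repeatDensity Mark co-placement probability and target
#'   repeat coverage.
#' @param exprSd,exprShift,exprSe Expression model (log2 scale).
#' @param nMirnas,nEnrichedMirnas,implantRate,seedRule miRNA model.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed,
                             chromLengths = c(chr1 = 1200000,
                                              chr2 = 1000000,
                                              chr3 = 800000),
                             nGenes = 240, fractionActive = 0.5,
                             nTssPeaks = 360, nBackgroundPeaks = 120,
                             offsetMean = 0, offsetSd = 400,
                             effectOffset = 111, effectSd = 20,
                             peakWidthMean = 1000, peakWidthSd = 150,
                             minPeakWidth = 300,
                             k4Prob = 0.8, repeatDensity = 0.3,
                             exprSd = 0.3, exprShift = -0.5, exprSe = 0.15,
                             nMirnas = 50, nEnrichedMirnas = 5,
                             implantRate = 0.35,
                             seedRule = "7mer-m8") {
  new("SimulationConfig", seed = as.integer(seed),
      chromLengths = chromLengths, nGenes = as.integer(nGenes),
      fractionActive = fractionActive, nTssPeaks = as.integer(nTssPeaks),
      nBackgroundPeaks = as.integer(nBackgroundPeaks),
      offsetMean = offsetMean, offsetSd = offsetSd,
      effectOffset = as.numeric(effectOffset), effectSd = effectSd,
      peakWidthMean = peakWidthMean, peakWidthSd = peakWidthSd,
      minPeakWidth = minPeakWidth, k4Prob = k4Prob,
      repeatDensity = repeatDensity, exprSd = exprSd,
      exprShift = exprShift, exprSe = exprSe,
      nMirnas = as.integer(nMirnas),
      nEnrichedMirnas = as.integer(nEnrichedMirnas),
      implantRate = implantRate, seedRule = seedRule)
}

# Substream seed for output k; kept well below 2^31.
.subSeed <- function(seed, k)
  (as.integer(seed) %% 1000000L) * 1013L + k * 7919L

#' Implant miRNA seed-match sites into DNA sequences
#'
#' For each sequence and each miRNA independently, with probability
#' `implant_rate` one seed-match site (the DNA match motif of
#' [seedMatchMotif()], on a random strand) is written at a random position
#' of the sequence. Sequences shorter than the site are skipped and
#' counted. Fully determined by `seed`.
#'
#' @param sequences `DNAStringSet`.
#' @param mirnas `RNAStringSet` of the miRNAs whose sites to implant.
#' @param implant_rate Per-sequence, per-miRNA implantation probability in
#'   `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param rule Seed rule (see [seedMatchMotif()]).
#' @return list with `sequences` (modified copy), `counts` (integer per
#'   miRNA: implanted sites), and `skipped` (sequences too short).
#' @export
implantSeedSites <- function(sequences, mirnas, implant_rate, seed,
                             rule = c("7mer-m8", "6mer", "8mer")) {
  rule <- match.arg(rule)
  if (implant_rate < 0 || implant_rate > 1)
    stop("implant_rate must lie in [0, 1]")
  motifs <- lapply(seq_along(mirnas), function(i)
    seedMatchMotif(mirnas[[i]], rule))
  counts <- integer(length(mirnas))
  names(counts) <- if (!is.null(names(mirnas))) names(mirnas)
                   else paste0("mirna_", seq_along(mirnas))
  skipped <- 0L
  out <- as.character(sequences)
  withSeed(seed, {
    for (i in seq_along(out)) {
      for (m in seq_along(motifs)) {
        if (runif(1L) >= implant_rate) next
        motif <- motifs[[m]]
        sl <- length(motif)
        if (nchar(out[i]) < sl) {
          skipped <- skipped + 1L
          next
        }
        site <- as.character(if (runif(1L) < 0.5) motif
                             else reverseComplement(motif))
        pos <- sample.int(nchar(out[i]) - sl + 1L, 1L)
        substr(out[i], pos, pos + sl - 1L) <- site
        counts[m] <- counts[m] + 1L
      }
    }
  })
  if (skipped > 0L)
    warning(skipped, " sequence/miRNA pairs skipped: sequence shorter ",
            "than the site")
  seqs <- DNAStringSet(out)
  names(seqs) <- names(sequences)
  list(sequences = seqs, counts = counts, skipped = skipped)
}

#' Simulate a complete synthetic dataset
#'
#' Generates the full input bundle of the analysis pipeline together with
#' its ground truth: chromosome sizes, gene models (BED12), a genome
#' sequence (FASTA), scored peaks with FDR (BED6+1) placed preferentially
#' near the TSSs of active genes, H3K4me3-style marks at active TSSs,
#' repeat and HOT-region annotations, a ChIP-qPCR-style validation table,
#' a knockdown expression table in which bound active genes are shifted
#' down by `exprShift`, and miRNA sequences whose seed-match sites are
#' implanted into bound sequence for the first `nEnrichedMirnas` miRNAs.
#' Bound, downregulated genes additionally receive one peak centred at
#' `effectOffset` bp from their TSS, the optimum the positional scan is
#' expected to recover.
#'
#' The run is fully determined by `config@seed`; calling twice with the
#' same configuration produces byte-identical files.
#'
#' @param config A [SimulationConfig-class].
#' @param dir Output directory (created if needed); `NULL` skips writing
#'   files and returns in-memory objects only.
#' @param sequences Generate the genome sequence and implant miRNA sites
#'   (default: yes when `dir` is given). Skipping them makes replicated
#'   simulations for interval-level analyses much cheaper.
#' @return list with the in-memory objects (`sizes`, `genes`, `peaks`,
#'   `k4`, `repeats`, `hot`, `expression`, `validation`, `mirnas`,
#'   `genome` when generated), `truth` (per-gene flags, per-peak
#'   provenance, per-miRNA implant counts) and `paths` (when `dir` is
#'   given).
#' @export
simulateDataset <- function(config, dir = NULL,
                            sequences = !is.null(dir)) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  lens <- config@chromLengths
  sizes <- Seqinfo(seqnames = names(lens), seqlengths = as.integer(lens))

  genes <- .simGenes(config, sizes)
  nG <- length(genes)

  # exactly round(nGenes * fractionActive) active genes, chosen at random,
  # so the peak-multiplicity constraint does not depend on sampling noise
  nActive <- as.integer(round(nG * config@fractionActive))
  active <- rep(FALSE, nG)
  if (nActive > 0L)
    active[withSeed(.subSeed(config@seed, 2L), sample(nG, nActive))] <- TRUE

  # peak-to-gene assignment (multiplicity <= 3 per active gene)
  if (nActive == 0L) {
    assignment <- integer(0)
  } else {
    if (config@nTssPeaks > 3L * nActive)
      stop("more TSS-proximal peaks requested (", config@nTssPeaks,
           ") than active genes x 3 (", 3L * nActive, ")")
    assignment <- withSeed(.subSeed(config@seed, 3L), {
      pool <- rep(which(active), 3L)
      sample(pool)[seq_len(config@nTssPeaks)]
    })
  }
  bound <- rep(FALSE, nG)
  bound[unique(assignment)] <- TRUE

  expression <- withSeed(.subSeed(config@seed, 4L), {
    lfc <- rnorm(nG, 0, config@exprSd)
    lfc[bound & active] <- lfc[bound & active] + config@exprShift
    p <- 2 * pnorm(-abs(lfc) / config@exprSe)
    data.frame(gene_id = mcols(genes)$gene_id,
               log2_fold_change = round(lfc, 6),
               p_value = round(p, 8))
  })
  # realized responsiveness at the canonical thresholds
  resp <- rep("none", nG)
  sig <- expression$p_value < 0.05
  resp[sig & expression$log2_fold_change > log2(1.2)] <- "up"
  resp[sig & expression$log2_fold_change < -log2(1.2)] <- "down"

  peaks <- .simPeaks(config, sizes, genes, assignment, resp)
  k4 <- .simK4(config, sizes, genes, active)
  repeats <- .simRepeats(config, sizes)
  hot <- .simHot(config, sizes)
  validation <- data.frame(fdr_lo = c(0, 0.02, 0.054, 0.1),
                           fdr_hi = c(0.02, 0.054, 0.1, 0.2),
                           n_tested = c(10L, 10L, 10L, 10L),
                           n_validated = c(10L, 9L, 5L, 2L))
  mirnas <- withSeed(.subSeed(config@seed, 8L), {
    txt <- vapply(seq_len(config@nMirnas), function(i)
      paste0(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
             collapse = ""), "")
    # enriched miRNAs share a 3'-half hexamer motif (AGUGCA or AGUGCU),
    # outside the seed region, mirroring the motif structure the analysis
    # is meant to rediscover
    if (config@nEnrichedMirnas > 0L) {
      for (i in seq_len(config@nEnrichedMirnas))
        substr(txt[i], 15L, 20L) <- sample(c("AGUGCA", "AGUGCU"), 1L)
    }
    ss <- RNAStringSet(txt)
    names(ss) <- sprintf("mir-%03d", seq_len(config@nMirnas))
    ss
  })

  genome <- NULL
  implant_counts <- NULL
  if (sequences) {
    genome <- withSeed(.subSeed(config@seed, 7L), {
      gs <- DNAStringSet(vapply(seq_along(lens), function(i)
        paste0(sample(c("A", "C", "G", "T"), lens[[i]], replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""), ""))
      names(gs) <- names(lens)
      gs
    })
    implant_counts <- setNames(integer(config@nMirnas), names(mirnas))
    if (config@nEnrichedMirnas > 0L && length(peaks) > 0L &&
        config@implantRate > 0) {
      # implant into the merged peak footprint so overlapping peaks never
      # overwrite each other's sites; the per-footprint rate preserves the
      # expected implantRate * n_peaks sites per enriched miRNA
      fp <- reduce(peaks, ignore.strand = TRUE)
      rate <- min(1, config@implantRate * length(peaks) / length(fp))
      enriched <- mirnas[seq_len(config@nEnrichedMirnas)]
      imp <- implantSeedSites(extractSequences(genome, fp), enriched,
                              rate, .subSeed(config@seed, 9L),
                              rule = config@seedRule)
      implant_counts[seq_len(config@nEnrichedMirnas)] <- imp$counts
      for (i in seq_along(fp)) {
        ch <- as.character(seqnames(fp))[i]
        subseq(genome[[ch]], start(fp)[i], end(fp)[i]) <-
          imp$sequences[[i]]
      }
    }
  }

  truth <- list(
    genes = data.frame(gene_id = mcols(genes)$gene_id, active = active,
                       bound = bound, responsive = resp),
    peaks = data.frame(name = mcols(peaks)$name,
                       type = mcols(peaks)$sim_type,
                       gene_id = mcols(peaks)$sim_gene,
                       offset = mcols(peaks)$sim_offset),
    mirnas = data.frame(
      mirna_id = names(mirnas),
      enriched = seq_len(config@nMirnas) <= config@nEnrichedMirnas,
      implanted_sites_peaks = if (is.null(implant_counts)) NA_integer_
                              else as.integer(implant_counts),
      implanted_sites_controls = 0L))

  out <- list(sizes = sizes, genes = genes,
              peaks = .stripSimCols(peaks), k4 = k4, repeats = repeats,
              hot = hot, expression = expression,
              validation = validation, mirnas = mirnas, genome = genome,
              truth = truth, config = config)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    writeLines(paste(names(lens), as.integer(lens), sep = "\t"),
               p("chrom.sizes"))
    writeGeneModels(genes, p("genes.bed"))
    writePeaks(out$peaks, p("peaks.bed"))
    writePeaks(k4, p("h3k4me3.bed"))
    writeLines(paste(as.character(seqnames(repeats)), start(repeats) - 1L,
                     end(repeats), mcols(repeats)$class, 0L, ".",
                     sep = "\t"), p("repeats.bed"))
    writeLines(paste(as.character(seqnames(hot)), start(hot) - 1L,
                     end(hot), sep = "\t"), p("hot_regions.bed"))
    write.table(expression, p("expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(validation, p("validation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeXStringSet(mirnas, p("mirnas.fa"))
    if (!is.null(genome)) writeXStringSet(genome, p("genome.fa"))
    write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
    out$paths <- c(chrom_sizes = p("chrom.sizes"), genes = p("genes.bed"),
                   peaks = p("peaks.bed"), h3k4me3 = p("h3k4me3.bed"),
                   repeats = p("repeats.bed"), hot = p("hot_regions.bed"),
                   expression = p("expression.tsv"),
                   validation = p("validation.tsv"),
                   mirnas = p("mirnas.fa"),
                   genome = if (!is.null(genome)) p("genome.fa") else NA,
                   truth = p("truth.json"))
  }
  out
}

.stripSimCols <- function(peaks) {
  keep <- setdiff(names(mcols(peaks)), c("sim_type", "sim_gene",
                                         "sim_offset"))
  p <- peaks
  mcols(p) <- mcols(p)[keep]
  p
}

# Gene models laid out left to right per chromosome, 2-5 exons each,
# fixed UTR lengths (150 nt 5', 250 nt 3') in mRNA space.
.simGenes <- function(config, sizes) {
  lens <- config@chromLengths
  quota <- diff(c(0L, round(cumsum(lens / sum(lens)) * config@nGenes)))
  withSeed(.subSeed(config@seed, 1L), {
    recs <- list()
    gid <- 0L
    for (ci in seq_along(lens)) {
      L <- lens[[ci]]
      pos <- 10000L
      for (gi in seq_len(quota[ci])) {
        pos <- pos + as.integer(round(runif(1L, 1500, 4500)))
        nex <- sample(2:5, 1L)
        ew <- as.integer(round(runif(nex, 350, 700)))
        iw <- if (nex > 1L) as.integer(round(runif(nex - 1L, 200, 1200)))
              else integer(0)
        txlen <- sum(ew) + sum(iw)
        if (pos + txlen > L - 10000L)
          stop("chromosome ", names(lens)[ci],
               " too short for its gene quota; enlarge it or lower nGenes")
        estart <- pos + cumsum(c(0L, head(ew, -1L) + iw))
        eend <- estart + ew - 1L
        strand <- sample(c("+", "-"), 1L)
        mlen <- sum(ew)
        utr5 <- 150L; utr3 <- 250L
        # CDS bounds in left-to-right exonic index space
        lo <- if (strand == "+") utr5 + 1L else utr3 + 1L
        hi <- mlen - if (strand == "+") utr3 else utr5
        gmap <- function(j) {  # left-to-right exonic index -> genomic
          cw <- cumsum(ew)
          e <- which(j <= cw)[1L]
          estart[e] + j - 1L - c(0L, cw)[e]
        }
        gid <- gid + 1L
        recs[[gid]] <- list(gene_id = sprintf("g%04d", gid),
                            chrom = names(lens)[ci],
                            start = pos, end = pos + txlen - 1L,
                            strand = strand,
                            exons = IRanges(estart, eend),
                            cds_start = gmap(lo), cds_end = gmap(hi))
        pos <- pos + txlen
      }
    }
    GeneModels(gene_id = vapply(recs, `[[`, "", "gene_id"),
               chrom = vapply(recs, `[[`, "", "chrom"),
               start = vapply(recs, `[[`, 0, "start"),
               end = vapply(recs, `[[`, 0, "end"),
               strand = vapply(recs, `[[`, "", "strand"),
               exons = IRangesList(lapply(recs, `[[`, "exons")),
               cds_start = vapply(recs, function(r)
                 as.integer(r$cds_start), 0L),
               cds_end = vapply(recs, function(r)
                 as.integer(r$cds_end), 0L),
               seqinfo = sizes)
  })
}

.simPeaks <- function(config, sizes, genes, assignment, resp) {
  lens <- config@chromLengths
  withSeed(.subSeed(config@seed, 5L), {
    tss <- tssPositions(genes)
    gplus <- as.character(strand(genes)) == "+"
    gchrom <- as.character(seqnames(genes))
    n_tss <- length(assignment)
    # first peak of each bound downregulated gene carries the effect offset
    first_of_gene <- !duplicated(assignment)
    is_effect <- first_of_gene & resp[assignment] == "down" &
      !is.na(config@effectOffset)
    offs <- numeric(n_tss)
    if (n_tss > 0) {
      offs <- round(rnorm(n_tss, config@offsetMean, config@offsetSd))
      offs[is_effect] <- round(rnorm(sum(is_effect), config@effectOffset,
                                     config@effectSd))
    }
    w <- pmax(config@minPeakWidth,
              round(rnorm(n_tss + config@nBackgroundPeaks,
                          config@peakWidthMean, config@peakWidthSd)))
    fdr_mix <- function(n, forced_good = rep(FALSE, n)) {
      good <- forced_good | runif(n) < 0.8
      ifelse(good, runif(n, 0, 0.05), runif(n, 0, 1))
    }
    chroms <- character(0); startv <- integer(0)
    if (n_tss > 0) {
      mid <- ifelse(gplus[assignment], tss[assignment] + offs,
                    tss[assignment] - offs)
      startv <- as.integer(pmax(1L, round(mid - w[seq_len(n_tss)] / 2)))
      chroms <- gchrom[assignment]
    }
    nb <- config@nBackgroundPeaks
    if (nb > 0) {
      bch <- sample(names(lens), nb, replace = TRUE,
                    prob = lens / sum(lens))
      wb <- w[n_tss + seq_len(nb)]
      bst <- vapply(seq_len(nb), function(i)
        sample.int(as.integer(lens[[bch[i]]] - wb[i]), 1L), 0L)
      chroms <- c(chroms, bch)
      startv <- c(startv, bst)
    }
    ntot <- n_tss + nb
    endv <- pmin(as.integer(startv + w - 1L),
                 as.integer(lens[chroms]))
    gr <- GRanges(chroms, IRanges(startv, endv), seqinfo = sizes)
    mcols(gr)$name <- sprintf("peak_%04d", seq_len(ntot))
    mcols(gr)$score <- round(runif(ntot, 20, 200), 1)
    mcols(gr)$fdr <- round(fdr_mix(ntot, c(is_effect, rep(FALSE, nb))), 6)
    mcols(gr)$sim_type <- c(rep("tss", n_tss), rep("background", nb))
    mcols(gr)$sim_gene <- c(mcols(genes)$gene_id[assignment],
                            rep(NA_character_, nb))
    mcols(gr)$sim_offset <- c(offs, rep(NA_real_, nb))
    gr
  })
}

.simK4 <- function(config, sizes, genes, active) {
  withSeed(.subSeed(config@seed, 6L), {
    tss <- tssPositions(genes)
    gplus <- as.character(strand(genes)) == "+"
    sel <- which(active & runif(length(genes)) < config@k4Prob)
    if (length(sel) == 0L) {
      gr <- GRanges(seqinfo = sizes)
      mcols(gr) <- DataFrame(name = character(), score = numeric(),
                             fdr = numeric())
      return(gr)
    }
    u <- round(runif(length(sel), 300, 700))
    d <- round(runif(length(sel), 1200, 1800))
    s <- ifelse(gplus[sel], tss[sel] - u, tss[sel] - d)
    e <- ifelse(gplus[sel], tss[sel] + d, tss[sel] + u)
    lens <- seqlengths(sizes)
    ch <- as.character(seqnames(genes))[sel]
    gr <- GRanges(ch, IRanges(pmax(1, s), pmin(e, as.numeric(lens[ch]))),
                  seqinfo = sizes)
    mcols(gr)$name <- sprintf("k4_%04d", seq_along(sel))
    mcols(gr)$score <- round(runif(length(sel), 20, 200), 1)
    mcols(gr)$fdr <- round(runif(length(sel), 0, 0.05), 6)
    sort(gr, ignore.strand = TRUE)
  })
}

.simRepeats <- function(config, sizes) {
  lens <- config@chromLengths
  classes <- data.frame(
    class = c("SINE", "LINE", "LTR", "low_complexity", "simple_repeat"),
    weight = c(0.45, 0.25, 0.15, 0.08, 0.07),
    min_len = c(150, 1000, 500, 50, 50),
    max_len = c(500, 3000, 1500, 200, 300))
  target <- config@repeatDensity * sum(lens)
  withSeed(.subSeed(config@seed, 10L), {
    # draw candidates in vectorized batches; drop any candidate that
    # overlaps an earlier-drawn one, accumulate until the coverage target
    acc <- GRanges(seqinfo = sizes)
    mcols(acc)$class <- character(0)
    mean_len <- sum(classes$weight * (classes$min_len + classes$max_len)) / 2
    for (round_i in 1:10) {
      deficit <- target - sum(width(acc))
      if (deficit <= 0) break
      n <- max(50L, ceiling(1.5 * deficit / mean_len))
      ci <- sample(seq_along(lens), n, replace = TRUE,
                   prob = lens / sum(lens))
      cl <- sample(nrow(classes), n, replace = TRUE, prob = classes$weight)
      wlen <- as.integer(round(runif(n, classes$min_len[cl],
                                     classes$max_len[cl])))
      s <- floor(runif(n, 1, lens[ci] - wlen))
      cand <- GRanges(names(lens)[ci], IRanges(s, width = wlen),
                      seqinfo = sizes)
      mcols(cand)$class <- classes$class[cl]
      hits <- findOverlaps(cand, cand)
      bad <- unique(queryHits(hits)[queryHits(hits) > subjectHits(hits)])
      cand <- cand[setdiff(seq_len(n), bad)]
      cand <- cand[!overlapsAny(cand, acc)]
      keep <- cumsum(as.numeric(width(cand))) <= deficit + mean_len
      acc <- c(acc, cand[keep])
    }
    sort(acc, ignore.strand = TRUE)
  })
}

.simHot <- function(config, sizes) {
  lens <- config@chromLengths
  withSeed(.subSeed(config@seed, 11L), {
    n <- 8L
    ch <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    w <- round(runif(n, 5000, 20000))
    s <- vapply(seq_len(n), function(i)
      sample.int(as.integer(lens[[ch[i]]] - w[i]), 1L), 0L)
    sort(GRanges(ch, IRanges(s, width = w), seqinfo = sizes),
         ignore.strand = TRUE)
  })
}
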