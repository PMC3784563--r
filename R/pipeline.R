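## End-to-end orchestration: explicit configuration, staged execution,
## per-stage TSV outputs, a JSON summary of the headline statistics and a
## plain-text log. Identical configuration + inputs give a byte-identical
## summary.

#' Build a fully materialized pipeline configuration
#'
#' Every threshold is made explicit here; downstream stages never apply
#' implicit defaults. Paths may point at a [simulateDataset()] bundle or
#' at real data in the same formats. Either `fdr_cutoff` or a validation
#' table (+ `min_validation_rate`) must be provided.
#'
#' @param peaks,genes,chrom_sizes Required input paths.
#' @param genome,h3k4me3,repeats,hot_regions,expression,mirnas,
#'   validation_table Optional input paths; stages needing a missing input
#'   are skipped (or fail when explicitly requested).
#' @param fdr_cutoff Peak FDR cutoff; `NULL` to derive it from the
#'   validation table.
#' @param min_validation_rate Minimum validation rate for cutoff selection.
#' @param flank_width Promoter / 3' flank width (bp).
#' @param tss_window,tss_bin TSS histogram half-window and bin width (bp).
#' @param k4_window TSS proximity window for mark co-occurrence (bp).
#' @param abg_windows Bound-gene TSS windows (bp).
#' @param fc_threshold,p_threshold Responsive-gene thresholds.
#' @param scan_window Positional scan half-width (bp).
#' @param fold_cutoff,alpha miRNA enrichment call thresholds.
#' @param seed_rule miRNA seed rule.
#' @param repeat_genome_fractions Named numeric of genome repeat-class
#'   fractions; computed from the repeat annotation when `NULL`.
#' @param seed RNG seed (matched-control sampling).
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(peaks, genes, chrom_sizes, genome = NULL,
                           h3k4me3 = NULL, repeats = NULL,
                           hot_regions = NULL, expression = NULL,
                           mirnas = NULL, validation_table = NULL,
                           fdr_cutoff = NULL, min_validation_rate = 0.8,
                           flank_width = 5000, tss_window = 5000,
                           tss_bin = 100, k4_window = 1000,
                           abg_windows = c(5000, 1000, 500),
                           fc_threshold = 1.2, p_threshold = 0.05,
                           scan_window = 5000, fold_cutoff = 1.5,
                           alpha = 0.05, seed_rule = "7mer-m8",
                           repeat_genome_fractions = NULL, seed = 1L) {
  if (is.null(fdr_cutoff) && is.null(validation_table))
    stop("provide fdr_cutoff or a validation_table to derive it from")
  cfg <- list(peaks = peaks, genes = genes, chrom_sizes = chrom_sizes,
              genome = genome, h3k4me3 = h3k4me3, repeats = repeats,
              hot_regions = hot_regions, expression = expression,
              mirnas = mirnas, validation_table = validation_table,
              fdr_cutoff = fdr_cutoff,
              min_validation_rate = min_validation_rate,
              flank_width = flank_width, tss_window = tss_window,
              tss_bin = tss_bin, k4_window = k4_window,
              abg_windows = abg_windows, fc_threshold = fc_threshold,
              p_threshold = p_threshold, scan_window = scan_window,
              fold_cutoff = fold_cutoff, alpha = alpha,
              seed_rule = seed_rule,
              repeat_genome_fractions = repeat_genome_fractions,
              seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipelineConfig()].
#' @return A `"pipelineConfig"` list with all defaults materialized.
#' @export
readPipelineConfig <- function(path) {
  vals <- read_yaml(path)
  do.call(pipelineConfig, vals)
}

# FNV-1a 32-bit hash of a string, reported as 8 hex digits; used to stamp
# the effective configuration into the log. Arithmetic kept in doubles,
# split at 16 bits so products stay inside the exact-double range.
.fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- filter, annotate, enrich, TSS profile,
#' integrate with expression, miRNA target-site enrichment -- writing
#' per-stage TSVs, a JSON summary of the headline statistics and a log to
#' `out_dir`. Stages whose optional inputs are absent are skipped and
#' recorded as such. A stage failure aborts with the stage name and cause.
#'
#' @param config A `"pipelineConfig"` (or YAML path).
#' @param out_dir Output directory.
#' @param stages Stages that must run: subset of `c("filter", "annotate",
#'   "enrich", "tss", "integrate", "mirna")`. By default optional stages
#'   run when their inputs are configured and are skipped otherwise;
#'   explicitly requesting a stage whose inputs are missing is a
#'   configuration error.
#' @return The summary, invisibly (also written as `summary.json`).
#' @export
runPipeline <- function(config, out_dir, stages = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  if ("integrate" %in% stages && is.null(config$expression))
    stop("configuration error: integrate stage requested but no ",
         "expression table configured")
  if ("mirna" %in% stages &&
      (is.null(config$mirnas) || is.null(config$genome)))
    stop("configuration error: mirna stage requested but miRNA FASTA ",
         "or genome sequence missing")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(config = unclass(config))
  note("config hash ", .fnv1a(toJSON(unclass(config), auto_unbox = TRUE,
                                     null = "null")),
       "; seed ", config$seed)
  tsv <- function(df, f) write.table(df, file.path(out_dir, f),
                                     sep = "\t", quote = FALSE,
                                     row.names = FALSE)

  ## -- filter --
  res <- stage("filter", {
    sizes <- readChromSizes(config$chrom_sizes)
    peaks <- readPeaks(config$peaks, seqinfo = sizes)
    cutoff <- config$fdr_cutoff
    if (is.null(cutoff)) {
      bins <- readValidationBins(config$validation_table)
      cutoff <- selectFdrCutoff(bins, config$min_validation_rate)
      if (is.na(cutoff))
        stop("no FDR cutoff passes the validation rate threshold")
    }
    kept <- filterPeaks(peaks, cutoff)
    list(sizes = sizes, peaks = kept, cutoff = cutoff,
         n_raw = length(peaks))
  })
  sizes <- res$sizes; peaks <- res$peaks
  summary$filter <- list(fdr_cutoff = res$cutoff, n_peaks_raw = res$n_raw,
                         n_peaks_filtered = length(peaks))
  ps <- summarizePeaks(peaks, sizes)
  summary$filter$spacing_kb <- ps$spacing_kb
  tsv(ps$density, "peak_density.tsv")
  note("filter: ", length(peaks), "/", res$n_raw,
       " peaks at FDR <= ", res$cutoff)

  ## -- annotate + enrich --
  genes <- stage("annotate", readGeneModels(config$genes, seqinfo = sizes))
  fm <- stage("annotate", partitionGenome(genes, sizes,
                                          config$flank_width))
  enr <- stage("enrich", featureComposition(peaks, fm, mode = "midpoint"))
  tsv(enr, "feature_enrichment.tsv")
  summary$enrichment <- list(
    ratios = setNames(as.list(enr$ratio), enr$feature))
  note("enrich: promoter ratio ",
       round(enr$ratio[enr$feature == "promoter"], 3))

  repeats <- NULL
  if (!is.null(config$repeats)) {
    repeats <- stage("enrich", {
      rr <- rtracklayer::import(config$repeats, format = "bed")
      mcols(rr)$class <- mcols(rr)$name
      rr
    })
    gf <- config$repeat_genome_fractions
    if (is.null(gf)) {
      glen <- sum(as.numeric(seqlengths(sizes)))
      cls <- unique(mcols(repeats)$class)
      gf <- vapply(cls, function(cl)
        sum(width(reduce(repeats[mcols(repeats)$class == cl]))) / glen, 0)
    }
    rc <- stage("enrich", repeatComposition(peaks, repeats, gf))
    tsv(rc, "repeat_enrichment.tsv")
    summary$repeats <- list(
      repetitive_fraction = 1 -
        rc$observed_fraction[rc$feature == "non_repetitive"])
  }

  dt <- stage("enrich", {
    genome <- if (!is.null(config$genome))
      readDNAStringSet(config$genome) else NULL
    if (!is.null(genome) || !is.null(repeats))
      tryCatch(buildDensityTable(peaks, genes, sizes, genome = genome,
                                 repeats = repeats),
               error = function(e) NULL)
    else NULL
  })
  if (!is.null(dt)) {
    tsv(dt, "density_table.tsv")
    if (nrow(dt) >= 5L) {
      reg <- regressPeakDensity(dt)
      tsv(reg$simple, "density_regression.tsv")
      summary$density <- list(
        gene_density_r2 =
          reg$simple$r_squared[reg$simple$covariate == "gene_density"],
        multiple_r2 = reg$multiple_r_squared)
    }
  }

  if (!is.null(config$hot_regions)) {
    hot <- stage("enrich",
                 rtracklayer::import(config$hot_regions, format = "bed"))
    ov <- overlapFraction(peaks, hot)
    summary$hot <- list(fraction_overlapping = ov$fraction,
                        jaccard = ov$jaccard)
  }

  ## -- tss --
  hist <- stage("tss", tssDistanceHistogram(peaks, genes,
                                            config$tss_window,
                                            config$tss_bin))
  tsv(data.frame(offset_bin_start = hist$breaks, count = hist$counts),
      "tss_histogram.tsv")
  d <- nearestTssDistances(peaks, genes)$distance
  summary$tss <- list(
    n_in_window = hist$n_peaks_in_window,
    fraction_within_1kb = mean(abs(d) <= 1000, na.rm = TRUE))
  if (!is.null(config$h3k4me3)) {
    k4 <- stage("tss", readPeaks(config$h3k4me3, seqinfo = sizes))
    co <- tssMarkOverlap(peaks, k4, genes, config$k4_window)
    summary$tss$k4_overlap_fraction <- co$fraction
    note("tss: ", co$numerator, "/", co$denominator,
         " TSS-proximal peaks overlap the mark")
  }

  ## -- integrate --
  if (!is.null(config$expression)) {
    summary$integration <- stage("integrate", {
      expr <- readExpressionTable(config$expression)
      universe <- intersect(mcols(genes)$gene_id, expr$gene_id)
      expr <- expr[expr$gene_id %in% universe, ]
      abgs <- boundGenes(peaks, genes[mcols(genes)$gene_id %in% universe],
                         config$abg_windows)
      args <- responsiveGenes(expr, config$fc_threshold,
                              config$p_threshold)
      for (w in names(abgs))
        writeLines(abgs[[w]],
                   file.path(out_dir, paste0("abg_", w, "bp.txt")))
      writeLines(args$up, file.path(out_dir, "arg_up.txt"))
      writeLines(args$down, file.path(out_dir, "arg_down.txt"))
      W0 <- names(abgs)[1L]
      all_resp <- union(args$up, args$down)
      ov_all <- overlapTest(abgs[[W0]], all_resp, universe)
      ov_up <- overlapTest(abgs[[W0]], args$up, universe)
      ov_down <- overlapTest(abgs[[W0]], args$down, universe)
      scan <- positionalScan(peaks, genes, args$up, args$down, universe,
                             config$scan_window)
      tsv(scanToTable(scan), "positional_scan.tsv")
      list(n_abg = lapply(abgs, length),
           n_up = length(args$up), n_down = length(args$down),
           overlap_p = ov_all$p_value, overlap_k = ov_all$k,
           overlap_expected = ov_all$expected,
           overlap_p_up = ov_up$p_value, overlap_p_down = ov_down$p_value,
           fraction_up_bound = if (length(args$up))
             length(intersect(args$up, abgs[[W0]])) / length(args$up)
             else NA,
           fraction_down_bound = if (length(args$down))
             length(intersect(args$down, abgs[[W0]])) / length(args$down)
             else NA,
           scan = scanOptima(scan))
    })
    note("integrate: down argmin ",
         summary$integration$scan$argmin_down, " bp")
  }

  ## -- mirna --
  if (!is.null(config$mirnas) && !is.null(config$genome)) {
    summary$mirna <- stage("mirna", {
      genome <- readDNAStringSet(config$genome)
      mirnas <- readMiRNAs(config$mirnas)
      # sequence-level analysis runs on the merged peak footprint so that
      # overlapping peaks never double-count the same genomic sequence
      fp <- reduce(peaks, ignore.strand = TRUE)
      controls <- sampleMatchedControls(fp, sizes, seed = config$seed)
      peak_seqs <- extractSequences(genome, fp)
      ctrl_seqs <- extractSequences(genome, controls)
      tab <- mirnaEnrichmentTable(peak_seqs, ctrl_seqs, mirnas,
                                  rule = config$seed_rule,
                                  fold_cutoff = config$fold_cutoff,
                                  alpha = config$alpha)
      tsv(tab, "mirna_enrichment.tsv")
      enriched <- tab$mirna_id[tab$call == "enriched"]
      motif <- if (length(enriched) >= 2L)
        discoverMotif(mirnas[enriched]) else NULL
      list(n_enriched = sum(tab$call == "enriched"),
           n_depleted = sum(tab$call == "depleted"),
           motif = if (!is.null(motif)) list(
             consensus = motif$consensus,
             n_containing = motif$n_containing,
             n_with_two = motif$n_with_two,
             total_occurrences = motif$total_occurrences,
             homology_to_AGUGUU = motifHomology(
               .expandConsensusVariants(motif$consensus), "AGUGUU"))
           else NULL)
    })
    note("mirna: ", summary$mirna$n_enriched, " enriched / ",
         summary$mirna$n_depleted, " depleted")
  }

  # out_dir deliberately excluded from the summary so reruns in different
  # directories stay byte-identical
  write_json(summary, file.path(out_dir, "summary.json"),
             auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(summary)
}

# Expand a single-degenerate IUPAC consensus into its concrete variants
# (RNA alphabet), for homology scoring.
.expandConsensusVariants <- function(consensus) {
  expand <- c(A = "A", C = "C", G = "G", U = "U",
              M = "AC", R = "AG", W = "AU", S = "CG", Y = "CU", K = "GU")
  chars <- strsplit(consensus, "")[[1L]]
  opts <- lapply(chars, function(ch) strsplit(expand[[ch]], "")[[1L]])
  apply(expand.grid(opts, stringsAsFactors = FALSE), 1L,
        paste0, collapse = "")
}
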