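#' FeatureMap: a per-base feature labelling of a genome
#'
#' Assigns every base of every chromosome one of the labels in
#' [featureClasses()], resolved by precedence (promoter outranks all
#' gene-body classes, intergenic is the fallback). Built by
#' [partitionGenome()]; queried with [locateInterval()] and
#' [genomeComposition()].
#'
#' @slot labels A [S4Vectors::RleList-class] (one run-length-encoded factor
#'   per chromosome) giving the label of every base.
#' @slot composition Named numeric: total bp of each feature class over the
#'   whole genome. Sums exactly to the genome length.
#' @slot flankWidth Width in bp of the promoter (upstream of the TSS) and
#'   3' flank (downstream of the gene end) classes.
#'
#' @export
setClass("FeatureMap",
  representation(labels = "list", composition = "numeric",
                 flankWidth = "numeric"))

setValidity("FeatureMap", function(object) {
  msgs <- character()
  if (!all(names(object@composition) %in% .FEATURE_CLASSES))
    msgs <- c(msgs, "composition has labels outside featureClasses()")
  glen <- sum(vapply(object@labels, length, 0))
  if (!isTRUE(all.equal(sum(object@composition), glen)))
    msgs <- c(msgs, "composition bp totals must sum to the genome length")
  if (length(object@flankWidth) != 1L || object@flankWidth <= 0)
    msgs <- c(msgs, "flankWidth must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FeatureMap Total bp per feature class (named numeric, sums to
#'   the genome length).
#' @param fm A `FeatureMap`.
#' @export
genomeComposition <- function(fm) {
  stopifnot(is(fm, "FeatureMap"))
  fm@composition
}

#' @describeIn FeatureMap Promoter/3'-flank width (bp) used to build the map.
#' @export
flankWidth <- function(fm) {
  stopifnot(is(fm, "FeatureMap"))
  fm@flankWidth
}

setMethod("show", "FeatureMap", function(object) {
  glen <- sum(object@composition)
  cat("FeatureMap over", length(object@labels), "chromosome(s),",
      format(glen, big.mark = ","), "bp; flank width",
      object@flankWidth, "bp\n")
  frac <- object@composition / glen
  for (cls in names(object@composition))
    cat(sprintf("  %-17s %12s bp (%5.2f%%)\n", cls,
                format(object@composition[[cls]], big.mark = ","),
                100 * frac[[cls]]))
  invisible(object)
})

#' PositionalScanResult: per-offset enrichment of responsive genes
#'
#' Result of [positionalScan()]: for every 1-bp offset in `[-window, window]`
#' around TSSs, the hypergeometric upper-tail p-value for enrichment of the
#' up- and downregulated responsive gene sets among the genes bound at that
#' offset (a gene is bound at offset d when some peak covers TSS + d in gene
#' orientation).
#'
#' @slot offsets Integer vector of signed offsets, `-window:window`.
#' @slot pUp,pDown Numeric p-value curves, same length as `offsets`.
#' @slot nBound Integer: number of universe genes bound at each offset.
#' @slot kUp,kDown Integer: bound genes that are up-/downregulated.
#' @slot universeSize,nUp,nDown Integer scalars describing the gene universe
#'   and the responsive set sizes.
#' @slot argminUp,argminDown Offset (bp) of the minimal p-value per
#'   direction; ties resolved toward the smallest absolute offset, then the
#'   positive side.
#' @slot minPUp,minPDown The minimal p-values.
#'
#' @export
setClass("PositionalScanResult",
  representation(offsets = "integer", pUp = "numeric", pDown = "numeric",
                 nBound = "integer", kUp = "integer", kDown = "integer",
                 universeSize = "integer", nUp = "integer", nDown = "integer",
                 argminUp = "integer", argminDown = "integer",
                 minPUp = "numeric", minPDown = "numeric"))

setValidity("PositionalScanResult", function(object) {
  n <- length(object@offsets)
  if (length(object@pUp) != n || length(object@pDown) != n ||
      length(object@nBound) != n)
    return("offset, p and count vectors must have identical length")
  if (any(object@pUp <= 0 | object@pUp > 1) ||
      any(object@pDown <= 0 | object@pDown > 1))
    return("p-values must lie in (0, 1]")
  TRUE
})

setMethod("show", "PositionalScanResult", function(object) {
  cat("PositionalScanResult:", length(object@offsets), "offsets",
      sprintf("[%+d, %+d]\n", min(object@offsets), max(object@offsets)))
  cat(sprintf("  universe %d genes; %d up / %d down responsive\n",
              object@universeSize, object@nUp, object@nDown))
  cat(sprintf("  down curve: min p = %.3g at %+d bp\n",
              object@minPDown, object@argminDown))
  cat(sprintf("  up   curve: min p = %.3g at %+d bp\n",
              object@minPUp, object@argminUp))
  invisible(object)
})

#' @describeIn PositionalScanResult Coerce the scan to a data.frame with
#'   columns offset, n_bound, k_up, k_down, p_up, p_down.
#' @param x A `PositionalScanResult`.
#' @export
scanToTable <- function(x) {
  stopifnot(is(x, "PositionalScanResult"))
  data.frame(offset = x@offsets, n_bound = x@nBound,
             k_up = x@kUp, k_down = x@kDown,
             p_up = x@pUp, p_down = x@pDown)
}

#' @describeIn PositionalScanResult Argmin offsets and minimal p-values as a
#'   named list (`argmin_up`, `min_p_up`, `argmin_down`, `min_p_down`).
#' @export
scanOptima <- function(x) {
  stopifnot(is(x, "PositionalScanResult"))
  list(argmin_up = x@argminUp, min_p_up = x@minPUp,
       argmin_down = x@argminDown, min_p_down = x@minPDown)
}

#' SimulationConfig: parameters of the synthetic dataset generator
#'
#' Holds every tunable of [simulateDataset()]. Defaults describe the study
#' conditions the package emulates: a multi-megabase multi-chromosome toy
#' genome, ~1 kb peaks concentrated near the TSSs of active genes (Normal
#' offsets, sd 400 bp), an activating factor whose knockdown downregulates
#' bound genes (log2 shift -0.5), binding effect centred at +111 bp
#' downstream of the TSS, H3K4me3-like marks co-placed at active TSSs, and
#' target sites of a subset of miRNAs implanted into bound sequence.
#' Construct with [simulationConfig()].
#'
#' @slot seed Master RNG seed (mandatory). Per-output substreams are derived
#'   from it so adding one output never perturbs the others.
#' @slot chromLengths Named numeric, chromosome lengths in bp.
#' @slot nGenes Number of gene models to place.
#' @slot fractionActive Fraction of genes flagged transcriptionally active.
#' @slot nTssPeaks,nBackgroundPeaks TSS-proximal and background peak counts.
#' @slot offsetMean,offsetSd Normal distribution (bp) of TSS-proximal peak
#'   midpoint offsets from the generating gene's TSS.
#' @slot effectOffset,effectSd Placement (bp) of the dedicated peak of bound,
#'   downregulated genes; the optimum the positional scan should recover.
#'   Set `effectOffset = NA` to disable the dedicated placement.
#' @slot peakWidthMean,peakWidthSd,minPeakWidth Peak width model (bp).
#' @slot k4Prob Probability that an active TSS carries an H3K4me3-like mark.
#' @slot repeatDensity Target fraction of the genome covered by repeats.
#' @slot exprSd Baseline log2 fold-change standard deviation.
#' @slot exprShift Knockdown log2 fold-change shift applied to bound active
#'   genes (negative: bound genes go down when the factor is depleted).
#' @slot exprSe Per-gene standard error used to convert log2 fold changes
#'   into p-values.
#' @slot nMirnas,nEnrichedMirnas Number of miRNAs emitted / with implanted
#'   target sites.
#' @slot implantRate Expected implanted sites per peak sequence for each
#'   enriched miRNA.
#' @slot seedRule miRNA seed-match rule ("7mer-m8", "6mer" or "8mer").
#'
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", chromLengths = "numeric",
                 nGenes = "integer", fractionActive = "numeric",
                 nTssPeaks = "integer", nBackgroundPeaks = "integer",
                 offsetMean = "numeric", offsetSd = "numeric",
                 effectOffset = "numeric", effectSd = "numeric",
                 peakWidthMean = "numeric", peakWidthSd = "numeric",
                 minPeakWidth = "numeric", k4Prob = "numeric",
                 repeatDensity = "numeric", exprSd = "numeric",
                 exprShift = "numeric", exprSe = "numeric",
                 nMirnas = "integer", nEnrichedMirnas = "integer",
                 implantRate = "numeric", seedRule = "character"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(object@chromLengths) < 1L || any(object@chromLengths <= 0) ||
      is.null(names(object@chromLengths)) ||
      anyDuplicated(names(object@chromLengths)))
    msgs <- c(msgs, "chromLengths must be named, unique and positive")
  for (s in c("fractionActive", "k4Prob", "repeatDensity"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      msgs <- c(msgs, paste(s, "must lie in [0, 1]"))
  if (object@implantRate < 0)
    msgs <- c(msgs, "implantRate must be non-negative")
  if (object@exprShift > 0)
    msgs <- c(msgs, "exprShift must be <= 0 (knockdown downregulates bound genes)")
  if (!object@seedRule %in% c("7mer-m8", "6mer", "8mer"))
    msgs <- c(msgs, "seedRule must be one of 7mer-m8, 6mer, 8mer")
  if (object@nEnrichedMirnas > object@nMirnas)
    msgs <- c(msgs, "nEnrichedMirnas cannot exceed nMirnas")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed", object@seed, "):",
      length(object@chromLengths), "chromosomes,",
      format(sum(object@chromLengths), big.mark = ","), "bp;",
      object@nGenes, "genes (", 100 * object@fractionActive, "% active )\n")
  cat(sprintf("  peaks: %d TSS-proximal (offset N(%g, %g)) + %d background\n",
              object@nTssPeaks, object@offsetMean, object@offsetSd,
              object@nBackgroundPeaks))
  cat(sprintf("  effect: offset %+g bp (sd %g), expression shift %g log2\n",
              object@effectOffset, object@effectSd, object@exprShift))
  cat(sprintf("  miRNAs: %d (%d enriched, implant rate %g, rule %s)\n",
              object@nMirnas, object@nEnrichedMirnas, object@implantRate,
              object@seedRule))
  invisible(object)
})
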