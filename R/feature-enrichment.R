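## Peak composition over feature classes, repeat classes and chromosomes,
## with exact binomial enrichment statistics and OLS regressions.

# Shared enrichment table builder: observed counts vs genome fractions.
# Two-sided exact binomial test with null probability = genome fraction;
# p clamped at the smallest positive double so log10_p is always finite.
.enrichmentTable <- function(observed, genome_fraction) {
  stopifnot(identical(names(observed), names(genome_fraction)))
  n <- sum(observed)
  obs_frac <- if (n > 0) observed / n else observed * 0
  ratio <- ifelse(genome_fraction > 0, obs_frac / genome_fraction,
                  ifelse(obs_frac > 0, Inf, NA_real_))
  if (any(is.infinite(ratio)))
    warning("class with zero genome fraction but observed counts; ",
            "ratio reported as Inf")
  p <- vapply(seq_along(observed), function(i) {
    if (genome_fraction[i] <= 0 || genome_fraction[i] >= 1 || n == 0)
      return(NA_real_)
    binom.test(round(observed[i]), round(n), genome_fraction[i],
               alternative = "two.sided")$p.value
  }, 0)
  p_clamped <- pmax(p, .Machine$double.xmin)
  data.frame(feature = names(observed),
             observed_count = as.numeric(observed),
             observed_fraction = as.numeric(obs_frac),
             genome_fraction = as.numeric(genome_fraction),
             ratio = as.numeric(ratio),
             p_value = as.numeric(p_clamped),
             log10_p = log10(as.numeric(p_clamped)),
             row.names = NULL)
}

#' Feature-class composition of peaks with enrichment statistics
#'
#' Distributes peaks over the feature classes of a [FeatureMap-class] and
#' compares the observed composition with the genome-wide composition. In
#' `"midpoint"` mode each peak counts once, for the class at its midpoint;
#' in `"bp"` mode peak bases are apportioned to classes. Enrichment ratio
#' is observed fraction over genome fraction; significance is a two-sided
#' exact binomial test with the genome fraction as the null probability.
#'
#' @param peaks Peak `GRanges`.
#' @param fm A [FeatureMap-class] built on the same genome.
#' @param mode `"midpoint"` (default) or `"bp"`.
#' @return data.frame with one row per feature class: observed count (or
#'   bp), observed fraction, genome fraction, ratio, p-value and log10 p.
#' @export
featureComposition <- function(peaks, fm, mode = c("midpoint", "bp")) {
  mode <- match.arg(mode)
  gf <- genomeComposition(fm) / sum(genomeComposition(fm))
  if (mode == "midpoint") {
    labs <- locateInterval(fm, peaks, mode = "midpoint")
    obs <- table(factor(labs, levels = .FEATURE_CLASSES))
  } else {
    m <- locateInterval(fm, peaks, mode = "bp_composition")
    obs <- colSums(m * width(peaks))
  }
  obs <- setNames(as.numeric(obs), .FEATURE_CLASSES)
  .enrichmentTable(obs, gf)
}

#' Repeat-class composition of peak sequence
#'
#' Fraction of peak bases overlapping each repeat class, plus the
#' non-repetitive remainder (fractions sum to 1), compared with the
#' genome-wide abundance of each class. Overlapping repeat annotations are
#' resolved in favour of the first-listed class, with a warning.
#'
#' @param peaks Peak `GRanges` (internally reduced; fractions refer to the
#'   merged peak footprint).
#' @param repeats `GRanges` of repeat intervals with the class in
#'   `mcols()$class` (or the BED name column), e.g. `SINE`, `LINE`, `LTR`,
#'   `low_complexity`, `simple_repeat`, `other`.
#' @param genome_fractions Named numeric: genome fraction of each repeat
#'   class (the non-repetitive fraction is inferred as the complement).
#' @return data.frame as in [featureComposition()], classes plus
#'   `non_repetitive`.
#' @export
repeatComposition <- function(peaks, repeats, genome_fractions) {
  cls_col <- if (!is.null(mcols(repeats)$class)) mcols(repeats)$class
             else mcols(repeats)$name
  if (length(repeats) && is.null(cls_col))
    stop("repeats need a 'class' (or 'name') metadata column")
  classes <- names(genome_fractions)
  if (length(repeats) && !all(cls_col %in% classes))
    stop("repeat class missing from genome_fractions: ",
         setdiff(unique(cls_col), classes)[1L])
  pk <- reduce(peaks, ignore.strand = TRUE)
  total <- sum(width(pk))
  claimed <- GRanges()
  overlap_warned <- FALSE
  bp <- setNames(numeric(length(classes)), classes)
  for (cls in classes) {
    cr <- repeats[cls_col == cls]
    if (length(cr) == 0L) next
    crr <- reduce(cr, ignore.strand = TRUE)
    eff <- GenomicRanges::setdiff(crr, claimed, ignore.strand = TRUE)
    if (!overlap_warned && sum(width(eff)) < sum(width(crr))) {
      warning("overlapping repeat annotations resolved by first-listed class")
      overlap_warned <- TRUE
    }
    bp[cls] <- sum(width(GenomicRanges::intersect(pk, eff,
                                                  ignore.strand = TRUE)))
    claimed <- reduce(c(claimed, crr), ignore.strand = TRUE)
  }
  obs <- c(bp, non_repetitive = total - sum(bp))
  gf <- c(genome_fractions, non_repetitive = 1 - sum(genome_fractions))
  .enrichmentTable(obs, gf)
}

#' Per-chromosome peak density table
#'
#' One row per chromosome with peak density and gene density (per `window`
#' bp), GC% and repeat% covariates. GC% may be supplied directly or
#' computed from the genome sequence; repeat% from a repeat annotation.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene-model `GRanges`.
#' @param sizes `Seqinfo` of chromosome lengths.
#' @param genome Optional `DNAStringSet` named by chromosome, used to
#'   compute GC% when `gc` is not given.
#' @param gc Optional named numeric, GC percent per chromosome.
#' @param repeats Optional repeat `GRanges` used to compute repeat% when
#'   `repeat_pct` is not given.
#' @param repeat_pct Optional named numeric, repeat percent per chromosome.
#' @param window Density window in bp (default 1e5).
#' @return data.frame with columns `chrom`, `length`, `peak_density`,
#'   `gene_density`, `gc_pct`, `repeat_pct`.
#' @export
buildDensityTable <- function(peaks, genes, sizes, genome = NULL, gc = NULL,
                              repeats = NULL, repeat_pct = NULL,
                              window = 1e5) {
  chroms <- seqnames(sizes)
  lens <- as.numeric(seqlengths(sizes))
  if (is.null(gc)) {
    if (is.null(genome))
      stop("supply gc or a genome sequence to compute it from")
    missing <- setdiff(chroms, names(genome))
    if (length(missing))
      stop("no genome sequence for chromosome: ",
           paste(missing, collapse = ", "))
    gc <- vapply(chroms, function(ch)
      100 * sum(letterFrequency(genome[[ch]], c("G", "C"))) /
        length(genome[[ch]]), 0)
  }
  if (is.null(repeat_pct)) {
    if (is.null(repeats))
      stop("supply repeat_pct or a repeat annotation to compute it from")
    rr <- reduce(repeats, ignore.strand = TRUE)
    repeat_pct <- vapply(chroms, function(ch)
      100 * sum(width(rr[seqnames(rr) == ch])) /
        lens[match(ch, chroms)], 0)
  }
  missing <- setdiff(chroms, names(gc))
  if (length(missing))
    stop("missing GC%% covariate for chromosome: ",
         paste(missing, collapse = ", "))
  missing <- setdiff(chroms, names(repeat_pct))
  if (length(missing))
    stop("missing repeat%% covariate for chromosome: ",
         paste(missing, collapse = ", "))
  pk <- table(factor(as.character(seqnames(peaks)), levels = chroms))
  gn <- table(factor(as.character(seqnames(genes)), levels = chroms))
  data.frame(chrom = chroms, length = lens,
             peak_density = as.integer(pk) / lens * window,
             gene_density = as.integer(gn) / lens * window,
             gc_pct = as.numeric(gc[chroms]),
             repeat_pct = as.numeric(repeat_pct[chroms]),
             row.names = NULL)
}

#' Regress peak density on genomic covariates
#'
#' Ordinary least squares of per-chromosome peak density on each covariate
#' separately (simple regressions, one R-squared each) and on all
#' covariates jointly (multiple regression with per-coefficient t-tests).
#' Collinear covariates yield `NA` coefficients and are flagged.
#'
#' @param tab data.frame from [buildDensityTable()].
#' @param response Response column (default `"peak_density"`).
#' @param covariates Covariate columns (default gene density, GC%,
#'   repeat%).
#' @return A list with `simple` (data.frame covariate, slope, r_squared,
#'   p_value), `multiple` (data.frame term, estimate, std_error, p_value),
#'   `multiple_r_squared` and `collinear` (logical flag).
#' @export
regressPeakDensity <- function(tab, response = "peak_density",
                               covariates = c("gene_density", "gc_pct",
                                              "repeat_pct")) {
  covariates <- intersect(covariates, names(tab))
  if (nrow(tab) < 3L) stop("need at least 3 chromosomes for regression")
  simple <- do.call(rbind, lapply(covariates, function(cv) {
    fit <- lm(stats::reformulate(cv, response), data = tab)
    sm <- summary(fit)
    data.frame(covariate = cv, slope = coef(fit)[[2L]],
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2L, 4L], row.names = NULL)
  }))
  if (nrow(tab) < length(covariates) + 2L)
    stop("need at least ", length(covariates) + 2L,
         " chromosomes for the multiple regression")
  mfit <- lm(stats::reformulate(covariates, response), data = tab)
  sm <- summary(mfit)
  est <- coef(mfit)
  collinear <- anyNA(est)
  cm <- sm$coefficients
  multiple <- data.frame(term = names(est), estimate = as.numeric(est),
                         std_error = cm[match(names(est), rownames(cm)), 2L],
                         p_value = cm[match(names(est), rownames(cm)), 4L],
                         row.names = NULL)
  list(simple = simple, multiple = multiple,
       multiple_r_squared = sm$r.squared, collinear = collinear)
}

#' Overlap fraction and Jaccard index between two interval sets
#'
#' Fraction of query intervals with at least 1 bp of overlap with any
#' region, plus the base-pair Jaccard index of the two footprints.
#'
#' @param query,regions `GRanges`.
#' @return list with `fraction`, `jaccard`, `n_overlapping`, `n_query`.
#' @export
overlapFraction <- function(query, regions) {
  n <- length(query)
  hit <- overlapsAny(query, regions, ignore.strand = TRUE)
  qr <- reduce(query, ignore.strand = TRUE)
  rr <- reduce(regions, ignore.strand = TRUE)
  inter <- sum(width(GenomicRanges::intersect(qr, rr, ignore.strand = TRUE)))
  uni <- sum(width(GenomicRanges::union(qr, rr, ignore.strand = TRUE)))
  list(fraction = if (n) sum(hit) / n else NA_real_,
       jaccard = if (uni > 0) inter / uni else NA_real_,
       n_overlapping = sum(hit), n_query = n)
}
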