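# peakscape

Downstream analysis of ChIP-seq peak calls for a chromatin-associated
factor, integrated with knockdown expression profiling and miRNA
target-site prediction.

## The problem

When a protein such as a nuclear Argonaute is profiled by ChIP-seq, the
peak caller's output (scored intervals with per-peak FDR) is only the
start of the analysis. The questions that follow are the ones this
package answers:

* **Which peaks are trustworthy?** Independent ChIP-qPCR validation of
  peaks binned by FDR gives a validation rate per FDR range; the cutoff
  is the upper bound of the maximal prefix of bins whose rates stay
  above a chosen minimum, and peaks are filtered at `fdr <= cutoff`.
* **Where in the genome does the factor bind?** Every base of the genome
  is assigned one of seven feature classes — promoter, 5'UTR, coding
  exon, intron, 3'UTR, 3' flank (both flanks `w` bp wide, default
  5 kb), intergenic — with a fixed precedence for overlapping
  annotations. For a class occupying genome fraction `g`, observing `k`
  of `n` peaks in it is scored with the enrichment ratio
  `(k/n) / g` and a two-sided exact binomial test `k ~ Bin(n, g)`.
  The same machinery covers repeat classes (SINE/LINE/LTR/low
  complexity/simple repeats) and per-chromosome peak densities, which
  are regressed (OLS) on gene density, GC% and repeat%.
* **Is binding promoter-centric?** Each peak midpoint gets a signed,
  strand-oriented distance to the nearest TSS; histograms over ±5 kb and
  co-occurrence with an active-promoter mark (H3K4me3) within ±1 kb
  quantify TSS targeting.
* **Does binding matter for expression?** Genes bound within ±5/±1/±0.5 kb
  of their TSS (AbGs) are intersected with genes responsive to factor
  knockdown (ArGs: fold change > 1.2, P < 0.05, split up/down). The
  overlap of two sets of sizes `a`, `b` drawn from a universe of `N`
  genes is tested with the hypergeometric upper tail
  `P(X >= k)`, `X ~ Hypergeom(N, a, b)`. A 1-bp **positional scan**
  then asks *where* binding matters: for every offset `d` in ±5 kb, the
  genes with a peak covering `TSS + d` are tested for enrichment of the
  up- and down-regulated sets, giving per-offset p-value curves and the
  offset of strongest association.
* **Could miRNAs guide the factor?** Peak sequences are scanned for
  seed-match sites (reverse complement of miRNA positions 2–8 by
  default, both strands, overlaps counted) and compared with
  length- and chromosome-matched random control regions. Per miRNA the
  site allocation is tested against `Bin(total, 1/2)`,
  Benjamini–Hochberg adjusted, and called enriched/depleted at a
  1.5-fold cutoff. A k-mer consensus scan over the enriched miRNAs
  (merging k-mer pairs differing at one position into IUPAC consensi)
  reports the most shared hexamer and its percent identity to the
  miR-29b nuclear-localization hexamer `AGUGUU`.

Everything is testable offline: `simulateDataset()` emits a complete toy
dataset (genome FASTA, BED12 gene models, BED6+1 peaks, marks, repeats,
HOT regions, expression table, miRNA FASTA) with ground truth, fully
determined by a seed.

## Worked example

```r
library(peakscape)
dir <- file.path(tempdir(), "demo")
sim <- simulateDataset(simulationConfig(seed = 42), dir = dir)

bins   <- readValidationBins(file.path(dir, "validation.tsv"))
cutoff <- selectFdrCutoff(bins, min_rate = 0.8)   # 0.054
peaks  <- filterPeaks(readPeaks(file.path(dir, "peaks.bed")), cutoff)

sizes <- readChromSizes(file.path(dir, "chrom.sizes"))
genes <- readGeneModels(file.path(dir, "genes.bed"))
fm    <- partitionGenome(genes, sizes, flank_width = 5000)
featureComposition(peaks, fm)[, c("feature", "observed_count",
                                  "ratio", "log10_p")]
#>             feature observed_count  ratio log10_p
#> 1          promoter            240  1.861 -28.991
#> 2    five_prime_utr             59 26.437 -62.319
#> 3       coding_exon             32  1.175  -0.493
#> 4            intron             22  0.637  -1.591
#> 5   three_prime_utr              3  0.764   0.000
#> 6 three_prime_flank              4  0.165  -6.269
#> 7        intergenic             45  0.245 -49.509

expr     <- readExpressionTable(file.path(dir, "expression.tsv"))
universe <- intersect(mcols(genes)$gene_id, expr$gene_id)
abg <- boundGenes(peaks, genes)[["5000"]]
arg <- responsiveGenes(expr)
overlapTest(abg, arg$down, universe)
#> 97 observed vs 87.0 expected shared genes (P = 0.0012)

positionalScan(peaks, genes, arg$up, arg$down, universe)
#> PositionalScanResult: 10001 offsets [-5000, +5000]
#>   universe 240 genes; 19 up / 111 down responsive
#>   down curve: min p = 8.67e-18 at +77 bp
#>   up   curve: min p = 0.0113 at -4834 bp
```

The simulated factor activates the genes it binds (knockdown shifts
bound genes down, log2 shift −0.5), binds promoters preferentially, and
its binding effect is implanted at +111 bp downstream of the TSS — which
the scan recovers (+77 bp here, well inside one peak half-width). 405 of
480 simulated peaks survive the validation-driven 0.054 cutoff; promoter
and 5'UTR classes are enriched, intergenic sequence depleted.

`runPipeline(pipelineConfig(...), out_dir)` chains all stages on a file
bundle and writes per-stage TSVs plus a JSON summary; reruns with the
same configuration and seed are byte-identical.

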