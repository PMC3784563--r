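---
title: "Methods: peak annotation, TSS-centric integration and miRNA target-site enrichment"
author: "peakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak annotation, TSS-centric integration and miRNA target-site enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical and design choices made where the
problem left them open, and the known limitations.

## Scope and data model

The package starts where a ChIP-seq peak caller stops. Its inputs are
scored peak intervals with a per-peak FDR (BED6+1), gene models (BED12 or
GTF), chromosome sizes, optional repeat/HOT-region annotations, a genome
FASTA, a knockdown differential-expression table, and mature miRNA
sequences. Internally everything lives in Bioconductor containers: peaks,
gene models and repeats are `GRanges`, sequences are `DNAStringSet` /
`RNAStringSet`, chromosome sizes a `Seqinfo`.

Coordinates are 1-based and closed throughout, the `GRanges` convention.
BED input and output (0-based, half-open) is converted at the I/O boundary
and nowhere else; GTF is already 1-based. Keeping a single internal
convention — the native one of the container library — removes the usual
source of off-by-one drift between modules.

A gene model carries its transcript span, strand, exons, and optional CDS
bounds. The TSS is the strand-oriented 5' end of the transcript: the
transcript start for `+` genes, the last transcribed base (transcript end)
for `-` genes. Each gene contributes exactly one TSS; collapsing multiple
isoforms to a major TSS is the caller's responsibility upstream of the
package.

## Validation-driven FDR cutoff

Peak callers report per-peak FDRs, but the working cutoff in a real study
comes from independent ChIP-qPCR validation of peaks sampled across FDR
ranges. `selectFdrCutoff()` formalizes that practice: bins are scanned in
increasing FDR order and the cutoff is the upper FDR bound of the last bin
in the *maximal prefix* of bins whose validation rates all reach
`min_rate`. The rule is deliberately conservative — a single failing bin
ends the scan even if later bins recover, because a validation rate that
collapses and then apparently recovers at higher FDR is more plausibly
sampling noise than a real non-monotonicity. When even the first bin
fails, the function returns `NA` rather than inventing a cutoff.
`min_rate` has no principled universal default; the pipeline default of
0.8 reflects the common practice of requiring clear majorities of
validated sites. Filtering is inclusive (`fdr <= cutoff`), so peaks at
exactly the cutoff are retained.

## Genome partitioning and composition statistics

`partitionGenome()` assigns every base of the genome exactly one of seven
labels with a fixed precedence:

promoter > 5'UTR > coding exon > intron > 3'UTR > 3' flank > intergenic.

The promoter is the `flank_width` bp (default 5000) immediately upstream
of the TSS, strand-aware; the 3' flank is the same width downstream of the
gene end. Where annotations overlap — one gene's promoter inside another's
intron — the higher-precedence class wins. Promoter outranks everything
because promoter binding is the quantity of primary interest; an
alternative ordering would silently reattribute promoter-proximal peaks to
gene-body classes of overlapping neighbours. Genes without CDS annotation
contribute all their exons as `coding_exon` and no UTR classes: an
explicit degenerate-input rule rather than a guess at UTR boundaries.
The per-base labelling is stored run-length-encoded per chromosome, and
its class totals always sum exactly to the genome length (a validity
condition of the `FeatureMap` class).

Peaks are located in the map either by midpoint (one peak, one class;
the default for peak-count composition) or by base-pair apportionment
(used for repeat composition, which is conventionally reported as
sequence fractions). Both modes exist because peak-count and
sequence-fraction summaries answer slightly different questions and
neither subsumes the other.

Enrichment of a class occupying genome fraction $g$, with $k$ of $n$
peaks (or bases) observed in it, is reported as the ratio $(k/n)/g$ with a
two-sided exact binomial test of $k \sim \mathrm{Bin}(n, g)$. The binomial
is the natural reference model once peaks are treated as independent
draws over the genome; no distributional asymptotics are involved, so it
remains exact for small classes. P-values are clamped at the smallest
positive double and `log10_p` is derived from the clamped value, so the
log-scale output is always finite even where the double-precision p-value
underflows; the extreme raw values are reported only as clamped sentinels.
For per-chromosome analyses, `buildDensityTable()` assembles peak density,
gene density, GC% and repeat% per chromosome (densities per 100 kb), and
`regressPeakDensity()` runs ordinary least squares per covariate
(simple $R^2$) and jointly (multiple regression with per-coefficient
t-tests); collinear covariates surface as `NA` coefficients with a flag
rather than an error.

## TSS-centric profiling

Each peak is reduced to its midpoint (`floor((start+end)/2)` in 0-based
terms) and assigned the signed distance to the nearest TSS in gene
orientation: 0 at the TSS base, positive into the gene. Nearest is by
absolute distance; exact ties break toward the downstream (positive) side,
then by gene order — an arbitrary but deterministic rule, stated here
because no convention is standard. Histograms cover ±`window` (default
5 kb) in bins of `bin_width`; the single distance exactly at `+window`
falls into the last bin so the histogram total equals the count of peaks
within the window.

Mark co-occurrence (`tssMarkOverlap()`) takes the peaks whose midpoints
lie within ±1 kb of a TSS and reports the fraction sharing at least 1 bp
with any mark peak. Overlap is unqualified (no minimum fraction), matching
how such co-occurrence figures are usually quoted.

## Binding-expression integration

The gene universe is the intersection of the annotation with the
expression table: genes that cannot possibly appear in both sets are not
allowed to dilute the null. Bound genes (AbGs) at window $W$ are genes
with at least one peak *midpoint* within $W$ of their TSS (windows
±5/±1/±0.5 kb by default; the sets nest by construction). Responsive
genes (ArGs) pass strict thresholds — linear fold change $> 1.2$ (or
$< 1/1.2$ for the down set) and $p < 0.05$; values exactly at a threshold
are excluded. The fold-change dialect (linear vs log2) is declared by the
column name of the expression table and never sniffed from the values:
a misread dialect would silently corrupt every downstream statistic.

Set overlap is tested with the exact hypergeometric upper tail: for
$|A| = a$, $|B| = b$ in a universe of $N$, the p-value is
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, a, b)$, alongside the
expected overlap $ab/N$. The hypergeometric is the canonical exact null
for gene-set intersection under fixed set sizes.

The positional scan asks *where* binding associates with responsiveness.
For every offset $d \in [-W, +W]$ in 1-bp steps, a gene is bound at $d$
when some peak interval covers the base $\mathrm{TSS} + d$ in gene
orientation — interval cover, not midpoint distance. The two definitions
are intentionally different: windowed AbG sets attribute binding to genes,
while the scan attributes binding to positions, and a peak covers a range
of positions. Per offset and per direction the responsive set's
representation among the bound genes is tested with the same
hypergeometric upper tail; offsets binding no gene report $p = 1$ by
convention. Raw per-offset p-values are reported, as the curves are meant
to be read against a fixed threshold; neighbouring offsets are strongly
dependent (a 1 kb peak covers a thousand consecutive offsets), so
multiplicity correction across offsets would be both non-standard and
misleading, and is left to the caller. The reported optimum is the offset
of minimal p; ties break toward the smallest absolute offset, then the
positive side. The implementation accumulates per-gene covered-offset
intervals into difference arrays, so the full ±5 kb scan is two vectorized
hypergeometric evaluations over 10,001 offsets.

## miRNA target sites against matched controls

The target-site definition is seed complementarity: the DNA match motif is
the reverse complement of the miRNA seed under a configurable rule —
`7mer-m8` (positions 2–8, the default), `6mer` (2–7), or `8mer` (2–8 plus
an `A` appended at the site's 3' end, the canonical 8mer layout). Sites
are counted on both strands, overlapping occurrences all count, and `N`
never matches. Seed matching is the lowest-assumption target model; the
rule is a parameter precisely because no single prediction convention is
canonical.

Controls are sampled per peak: same chromosome, identical length, uniform
position, rejected if overlapping any excluded interval (by default the
peaks themselves), fully determined by the seed. GC matching within a
tolerance is available but off by default — length and chromosome matching
is the stated matching criterion, and GC rejection sampling can fail on
small genomes. Since peak and control footprints then have equal total
length, each miRNA's site allocation is tested against
$\mathrm{Bin}(\text{total}, 1/2)$ two-sided, BH-adjusted across miRNAs;
calls require both the adjusted p below $\alpha$ and the fold ratio beyond
the cutoff (1.5 by default, depletion symmetric at its reciprocal). When
both counts are zero the miRNA is neutral with $p = 1$; a zero control
count with nonzero peak count reports an infinite ratio sentinel.

In the orchestrated pipeline the sequence-level stage runs on the *merged*
peak footprint rather than on raw peaks: overlapping peaks would otherwise
duplicate the same genomic sequence into several "independent"
observations, inflating site-count variance and biasing the allocation
test. Deposited peak lists from real callers are non-overlapping, so this
makes no difference there.

Motif discovery over the enriched miRNAs enumerates all k-mers
(default $k = 6$), merges every pair differing at exactly one position
into an IUPAC-degenerate consensus (at most one degenerate position, so a
consensus matches exactly its two members), and returns the consensus
present in the most sequences; ties break by total occurrences, then
lexicographically. Reported alongside are the number of sequences with at
least two occurrences and the total occurrence count. `motifHomology()`
scores ungapped position-wise identity of consensus variants against a
reference hexamer (the miR-29b nuclear-localization signal `AGUGUU` in the
shipped analyses) and returns the best variant's percentage.

## The synthetic-data generator

`simulateDataset()` emits the complete input bundle with ground truth,
fully determined by the master seed; each output type draws from its own
substream derived from that seed, so adding an output never perturbs the
others. Its defaults are the emulated study conditions, chosen once:

* three chromosomes totalling 3 Mb; 240 genes with 2–5 exons, 150 nt
  5'UTRs and 250 nt 3'UTRs in mRNA space; exactly half the genes active;
* 360 TSS-proximal peaks (at most 3 per active gene) with midpoints at
  Normal(0, 400 bp) offsets from their gene's TSS, plus 120 background
  peaks placed uniformly; widths Normal(1000, 150) bp, floored at 300 bp,
  matching the ~1 kb scale typical of transcription-factor-like peaks;
* per-peak FDRs from a mixture (80% Uniform(0, 0.05), 20% Uniform(0, 1))
  so FDR filtering always has something to remove; the emitted validation
  table has a bin edge at 0.054 with rates 1.0/0.9/0.5/0.2 over ten tested
  peaks per bin, so the selection rule lands on 0.054 at
  `min_rate = 0.8`;
* an H3K4me3-like mark at active TSSs with probability 0.8, spanning
  roughly −500…+1500 bp around the TSS;
* repeats covering 30% of the genome across SINE/LINE/LTR/low-complexity/
  simple-repeat classes with class-typical length ranges; eight HOT-style
  regions;
* an expression model in which knockdown shifts *bound active* genes by
  −0.5 log2 units around a Normal(0, 0.3) baseline, with p-values derived
  from a per-gene standard error of 0.15 — so responsive calls emerge from
  the same thresholds the analysis applies rather than being labelled by
  fiat;
* one dedicated peak per bound, downregulated gene centred at
  +111 bp (sd 20) from the TSS — the positional optimum the scan is meant
  to recover;
* 50 miRNAs of 22 nt; the first five are "enriched": their seed-match
  sites are implanted into the merged peak footprint (per-sequence
  Bernoulli rate preserving an expectation of 0.35 sites per peak per
  enriched miRNA), and their 3' halves carry the shared hexamer
  (`AGUGCA`/`AGUGCU`) that motif discovery should find.

Implanting writes the match motif at a random position on a random strand;
counts are exact event counts, and a conservation test verifies they are
recovered by the site scanner when collisions are excluded by
construction. The generator does *not* emulate read-level data (no FASTQ,
no coverage pileups), realistic nucleotide composition (the genome is
i.i.d. with 60% AT), isoform structure, probe-level microarray noise, or
inter-gene correlation in expression. Passing tests therefore demonstrate
that the analysis machinery recovers planted structure of the kinds
listed — not that it is robust to alignment artifacts, copy-number
distortion, or annotation error in real data.

## Numerical choices and degenerate inputs

* Exact tests only (binomial, hypergeometric); no normal approximations
  anywhere, so small-class behaviour needs no special-casing.
* P-value clamping at `.Machine$double.xmin`; `log10_p` always finite.
* Empty inputs have defined results: no peaks gives empty bound sets and
  an `NA` spacing sentinel; no genes is an error for TSS analyses; an
  empty universe is an error for set tests; zero denominators return `NA`
  sentinels rather than `NaN`.
* All randomness (control sampling, implanting, simulation) is
  seed-parameterized through one helper that saves and restores the
  caller's RNG state, so library calls never perturb user sessions.
* Tie-breaks (nearest TSS, scan argmin, motif ranking) are deterministic
  and documented above.
* Test problem sizes were chosen to keep the full suite in single-digit
  minutes while leaving no statistical check underpowered: oracle
  equivalences run on ≤ 50 kb genomes and universes ≤ 30, calibration
  uses 1000 permutations and 200 null replicates, and parameter recovery
  uses 50 simulation replicates at the default study conditions.

## Known limitations

* The binomial composition test treats peaks as independent draws;
  clustered binding (e.g. several peaks in one promoter) makes it
  anti-conservative. The positional scan and overlap tests are
  gene-level and do not share this issue.
* Seed-match counting treats miRNAs independently, but miRNAs from one
  family share seeds, and an implanted site for one miRNA can create
  straddling sites for another whose motif overlaps it; enrichment calls
  for closely related miRNAs are therefore correlated.
* The matched-control null conditions on length and chromosome only (GC
  optional); composition differences between peaks and the genome
  background are not otherwise controlled.
* One transcript per gene: alternative TSSs must be collapsed upstream.
* The validation-driven cutoff rule is a formalization of practice, not a
  statistically optimal decision rule; its `min_rate` is a judgement call.
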