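---
title: "Methods: associating differential exon usage with differential histone modification"
author: "episplicer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: associating differential exon usage with differential histone modification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episplicer)
```

## The problem

Histone modifications near exon–intron junctions are thought to crosstalk
with the splicing machinery: chromatin readers recruited at a junction can
influence spliceosome assembly, so a change in a mark's occupancy between
two cell states may accompany a change in how strongly the neighbouring
exon is included. `episplicer` quantifies this coupling across a panel of
epigenomes. For every pair of cell types it asks, exon by exon, whether
*differential exon usage* (DEU, a change in the exon's share of its gene's
reads) co-occurs with *differential histone modification* (DHM, a change in
ChIP-seq peak density) in the 200-bp flanks of that exon, and it calls a
gene **epispliced** for a mark when the gene's per-exon DEU values
correlate strongly with the flank M-values.

The package is an integration layer: it does not re-implement a
negative-binomial GLM for exon usage or a Bayesian peak model. Its built-in
DEU and DHM statistics are deliberately simple, transparent stand-ins, and
import paths (`import_deu_table()`, `import_manorm_table()`) accept result
tables from the dedicated external tools for full-fidelity runs.

## Gene model

Transcript annotations are flattened per gene: the union of all transcript
exons is split at every distinct exon boundary (`flatten_gene_models()`),
giving disjoint *exon bins* numbered in ascending genomic order regardless
of strand. Strand enters only through the first-exon flag: a bin
overlapping the 5′-most exon of any transcript is marked and excluded from
flank derivation and usage testing, since signal there is dominated by
alternative-promoter regulation rather than splicing.

Four exclusion rules remove genes whose bins cannot be attributed cleanly
(`filter_gene_clusters()`): genes sharing exonic sequence with another
gene; duplicated gene ids (the same id annotated at two or more disjoint
transcript loci on one contig); multi-region genes (bins spanning more
than one contig or strand); and single-bin genes, for which relative usage
is undefined. The duplicated/multi-region split is our operationalization —
annotation pathologies of both kinds exist, and the retained set is
independent of the order in which the rules are applied.

Each retained non-first bin owns two flanks of `width` bp (default 200, a
conventional crosstalk range) on the intronic side of its junctions:
`[start − width, start)` and `[end, end + width)`, clipped at the contig
origin. Centered windows are a plausible alternative reading of "around
the junction"; we chose the intronic side so flank signal never overlaps
exon-body signal, and both the width and (via `include_first`) the bin
subset are configurable. Flanks are *not* truncated at neighbouring exons.
Internally all intervals are `GRanges` (1-based, closed); every text
artifact (BED, flat TSVs) is written 0-based half-open.

## Differential exon usage

`test_exon_usage()` pools replicate counts by summation per condition and,
for each bin, tests the 2×2 table (bin count vs rest-of-gene count,
condition A vs B) with a two-sided Fisher exact test. The effect size is
the usage log2 fold change

$$\mathrm{deu} = \log_2\frac{(b_B+0.5)/(r_B+0.5)}{(b_A+0.5)/(r_A+0.5)},$$

with 0.5 pseudocounts so the value stays finite at empty cells. Genes with
zero totals in a condition, or a single testable bin, are excluded (`NA`).
P-values are Benjamini–Hochberg adjusted within each comparison.

Two distinct thresholds act downstream (`apply_deu_significance()`): the
*significance flag* uses the FDR-adjusted p (default 0.05) and feeds the
odds-ratio analysis, while the *zeroing rule* sets `deu_value` to 0
wherever the raw p exceeds 0.05 before any correlation is computed, so
that clearly non-differential exons contribute exact zeros rather than
noise.

**Limitation.** Pooling replicates ignores biological overdispersion; under
replicate variability beyond multinomial sampling the exact test is
anticonservative, which is one reason the correlation stage re-tests at
the gene level and applies its own FDR. The test's p-values are verified
uniform-conservative under its own (multinomial) sampling model.

## Differential histone modification

`load_and_merge_peaks()` merges replicate peak files into maximal intervals
(overlapping *and* abutting intervals merge; replicate densities are
summed — the data rarely say how replicate densities were scaled, and
summation keeps ratios between samples unchanged).
`ma_normalize_and_test()` projects both samples' peaks onto their merged
union and computes, per reference peak with summed densities $x_A, x_B$:

$$M = \log_2\frac{x_A+0.5}{x_B+0.5}, \qquad
  A = \tfrac12\log_2\big[(x_A+0.5)(x_B+0.5)\big].$$

A straight-line baseline $M = a + bA$ is fitted on the *common* peaks
(≥1 bp overlap between both samples' peak sets) and subtracted, removing
library-size and intensity-dependent bias. Two numerical choices matter
here and were made after observing how ordinary fits fail:

* **Trimmed baseline.** Genuinely differential common peaks lie exactly on
  the line $M = 2A - 2\log_2 x_{\mathrm{unchanged}}$, i.e. they are
  *collinear high-leverage points*; a plain least-squares fit (and even a
  Theil–Sen fit, when the null peaks span a narrow A-range) tips toward
  them and compresses every normalized M. We therefore fit by iteratively
  trimmed least squares: start from the median level, discard points whose
  residual exceeds 3 robust SDs, refit, iterate.
* **Robust scale.** The z-test for $M'$ uses the median absolute deviation
  of the common-peak $M'$ rather than the standard deviation, so a
  minority of truly differential peaks does not inflate the null spread.

A peak is differential when `p_fdr <= 0.05` and `|M'| >= 1` (both
configurable). The z-test assumes one common scale; weak peaks are
noisier in log space than strong ones, which the simple model ignores —
another reason the hard `|M'|` floor is kept.

## Flank annotation

`annotate_flanks()` assigns a differential-peak record to a flank iff the
intervals overlap by at least 1 bp. Among several records on one flank the
smallest raw p wins (ties: larger `|M|`, then leftmost start — all
deterministic). The FDR correction is then *re-pooled per mark across all
(flank, comparison) records of the whole cohort*, reflecting that every
pairwise comparison draws from one family of tests. Workflows of this
kind map M-values onto the flanking regions of each exon without fixing
how two flank signals become one exon value, so
`reduce_to_exon_signal()` makes that reduction explicit: default `"min-p"` (the significant flank
with the smaller raw p), alternatives `"max-abs-M"` and `"mean"`. Exons
with no significant flank get an exact 0, and the table is completed so
every retained exon appears once per (comparison, mark).

## Association and epispliced calling

Co-occurrence is scored by the odds ratio of the exon-level 2×2 event
table,

$$OR = \frac{n_{00}\,n_{11}}{n_{10}\,n_{01}},$$

with a two-sided Fisher exact test, Haldane–Anscombe correction (+0.5 to
all cells, flagged) when a cell is empty, and a Woolf logit 95% CI.
The default event unit pools comparisons (an exon is DEU-flagged if
significant in ≥1 comparison; DHM-flagged likewise per mark, any-mark for
the pooled row); a per-comparison unit is available because the printed
tables do not pin the unit down. `grouped_association()` repeats the
analysis per gene or per term group with BH adjustment across groups and a
`BASELINE` row for the full scope.

`gene_deu_dhm_correlation()` pairs, per (gene, comparison, mark), the
zeroed DEU vector with the exon M vector over the gene's retained bins and
computes Pearson's R (Spearman selectable; in practice rank correlation
calls a subset of the Pearson calls). Genes with fewer than 3 paired exons
or a zero-variance vector are excluded; p-values come from the
t-transform of R and are BH-adjusted over all (gene, comparison, mark)
tests jointly. `call_epispliced()` requires `|R| >= 0.5` and
`p_fdr <= 0.05`; the sign of R is kept, and a call in comparison A-vs-B is
counted for both A and B when building the per-cell-type catalog.

## Cohort analysis

With $k$ cell types there are $\binom{k}{2}$ comparisons
(`enumerate_comparisons()`; 19 cell types give 171). Two filters restrict
attention to developmentally interesting events:

* **Non-ubiquity** (`ubiquity_filter()`): exons whose usage change passes a
  strict threshold (`p_fdr <= 1e-4`) in 1–25 comparisons are kept; exons
  differential nearly everywhere say little about specific transitions.
  The ceiling is configurable or derivable as the 95th percentile.
* **Pooled filter** (`pooled_filter()`): each cell type is tested
  one-vs-rest with the built-in statistic; exons never significant in any
  one-vs-rest analysis have their pairwise DEU values zeroed.

Cell types are compared by the Jaccard index of their epispliced gene
sets, $J = |E_1 \cap E_2|/|E_1 \cup E_2|$ (defined 0 when both sets are
empty), clustered hierarchically on distance $1-J$ (average linkage by
default; single/complete available — the choice is not dictated by the
method), and each labeling scheme (potency, sample type, germ-layer
origin, life stage) is scored by the adjusted Rand index after cutting the
dendrogram at k = number of distinct labels in that scheme. The ARI uses
the closed-form permutation-model pair-counting formula; a scheme with one
label is reported `NA`.

## Term enrichment

`term_enrichment()` is a one-sided hypergeometric over-representation test
per term, with fold enrichment $(k/n)/(K/N)$ and BH adjustment. The
background is the set of genes carrying either a DEU or a DHM event, so
enrichment reflects episplicing specifically rather than detectability.
The term map is taken as given (pre-expanded to ancestors or not, at the
caller's discretion); ontology graph handling is out of scope.

## The synthetic study generator

`simulate_dataset()` emits a complete miniature study — GTF annotation,
bin-by-sample counts, per-sample BED peak files, metadata, a term map —
plus the truth tables needed to score recovery. Defaults: 6 cell types ×
2 replicates × 300 genes, which runs the full pipeline in about a minute;
the test suite uses smaller panels (typically 4 × 2 × 50–60) for its
end-to-end checks.

What it emulates, and how:

* multi-transcript genes (identical, exon-skipping and boundary-shifted
  second transcripts) plus decoys that exercise every exclusion filter;
* gene totals drawn negative-binomial (mean 2000, dispersion 0.05) and
  allocated to bins by a Dirichlet-multinomial (concentration 100), so
  replicates carry realistic usage overdispersion;
* planted usage shifts of ±2 log2 units on ~40% of the exons of designated
  genes, active in the cell types of the gene's cohort group;
* peak read densities drawn Gamma-Poisson (negative binomial, size 20)
  around per-peak intrinsic strengths that are log-normal across peaks
  (log2 SD 1.2) and shared across cell types — real peak sets span orders
  of magnitude in density, and this spread is what anchors the MA
  baseline; intergenic background peaks provide the common-peak scaffold;
* the epigenetic coupling is planted at the summary level: for an
  epispliced gene's flank peaks the cell-level log2 density offset is
  `coupling_slope × usage_shift + N(0, dhm_noise_sd)` (defaults 1 and
  0.3, giving a planted coupling correlation near 0.95 before measurement
  noise); `coupling_slope = 0` is the null;
* uncoupled DEU-only and DHM-only genes, noise-only flank peaks on a fifth
  of the null genes, cell-type groups sharing epispliced-gene pools, and
  one term covering 80% of the planted epispliced genes versus 5% of the
  rest.

What it does **not** emulate: read-level data (no FASTQ/BAM, no mapping
bias), genome sequence, input/IgG control structure, peak-calling
artifacts, mark-specific peak shapes, or any mechanistic chromatin model.
Passing recovery tests therefore demonstrates that the integration logic
detects the planted statistical structure at realistic noise levels — not
that the biological coupling exists in any particular real data set.

`simulate_epispliced_catalog()` plants group structure directly at the
catalog level (per-cell-type gene sets with within-group retention 0.8 and
disjoint pools between groups) for clustering checks without the cost of
the full pipeline, and `score_recovery()` reports precision/recall of
epispliced calls, the clustering ARI against planted groups, and the
planted term's enrichment rank.

## Determinism and numerical conventions

Every stochastic step flows from a single integer seed; the same
parameters and seed reproduce byte-identical files. Pseudocounts are 0.5
throughout. All tie-breaks (best peak per flank, two-flank reduction) are
total orders, so results are independent of input row order. BH is used
wherever "FDR-adjusted" appears, with these pools: within-comparison (DEU),
per mark across flanks × comparisons (DHM flank signals), across groups
(gene/term ORs), and across genes × comparisons × marks (correlations).
Degenerate inputs are defined, not guessed at: empty contingency tables
error, `J(\varnothing,\varnothing) = 0`, single-label schemes give `NA`
ARI, identical samples produce no DHM calls.
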