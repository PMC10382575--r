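# episplicer

`episplicer` asks whether alternative splicing and chromatin rewiring go
hand in hand. Across all pairwise comparisons of a panel of epigenomes it
associates **differential exon usage** (DEU — a change in an exon's share
of its gene's reads) with **differential histone modification** (DHM — a
change in ChIP-seq peak density for marks such as H3K36me3 or H3K27ac) at
the 200-bp flanks of exon–intron junctions, and calls genes **epispliced**
when the two signals track each other. It is aimed at computational
epigenomics groups integrating RNA-seq exon counts with histone ChIP-seq
peak sets across many cell types.

## What it computes

* **Flattened exon model** — transcript exons are split at every boundary
  into disjoint numbered bins (first exons flagged and excluded), with
  filters for overlapping, duplicated, multi-region and single-exon genes,
  and 200-bp intronic flanks per retained bin.
* **DEU** — per bin and comparison, a two-sided exact test on (bin,
  rest-of-gene) × (condition A, B) pooled counts with usage log2 fold
  change `log2[(b_B+.5)/(r_B+.5)] − log2[(b_A+.5)/(r_A+.5)]`; or import of
  external DEU result tables.
* **DHM** — MA normalization of peak densities, `M = log2(x_A/x_B)` against
  a robust trimmed baseline in `A`, z-tests on a robust scale, calls at
  `p_FDR ≤ 0.05` and `|M| ≥ 1`; or import of external differential-peak
  tables.
* **Co-occurrence** — exon-level contingency tables scored by the odds
  ratio `OR = (n00·n11)/(n10·n01)` with Fisher exact tests, Woolf 95% CIs
  and Haldane correction, globally, per gene and per term group.
* **Epispliced calling** — per (gene, comparison, mark) Pearson correlation
  R between the zeroed DEU vector and flank M-values; calls at `|R| ≥ 0.5`
  and `p_FDR ≤ 0.05`, counted for both cell types of the comparison.
* **Cohort structure** — non-ubiquity (significant in 1–25 of the pairwise
  comparisons at `p_FDR ≤ 1e-4`) and pooled one-vs-rest filters; Jaccard
  similarity `J = |E1 ∩ E2| / |E1 ∪ E2|` of epispliced gene sets;
  hierarchical clustering on `1 − J` scored against label schemes by the
  adjusted Rand index.
* **Enrichment** — hypergeometric term over-representation against the
  background of genes with any DEU or DHM event.
* **Synthetic studies** — a seeded generator that emits a complete
  miniature study (GTF, counts, peak BEDs, metadata, term map) with
  planted DEU, coupling, cohort groups and an enriched term, plus
  truth tables and recovery scoring.

## Worked example

```r
library(episplicer)

# odds ratio from a published exon-event contingency table
contingency_odds_ratio(8198, 5149, 34585, 79888)[, c("or", "ci_low", "ci_high")]
#>      or ci_low ci_high
#> 1 3.678  3.544   3.817
```

An OR of 3.68 [3.54, 3.82] means an exon with a histone-mark change has
almost four times the odds of also being differentially used.

```r
# a miniature synthetic study, end to end
params <- simulation_params(n_cell_types = 4, n_genes = 60, n_epispliced = 6,
                            n_deu_only = 4, n_dhm_only = 4,
                            marks = "H3K36me3", n_background_peaks = 150,
                            seed = 42)
study <- simulate_dataset(params)
res <- run_pipeline(pipeline_config(study = study, seed = 42))
#> [episplicer] flattening annotation
#> [episplicer] pairwise DEU over 6 comparisons
#> [episplicer] 53 genes carry non-ubiquitous DEU exons
#> [episplicer] pooled one-vs-rest filter
#> [episplicer] pairwise DHM for mark(s): H3K36me3
#> [episplicer] annotating flanks
#> [episplicer] odds-ratio association and per-gene correlation
#> [episplicer] term enrichment on 6 epispliced genes

head(res$calls[res$calls$is_epispliced,
               c("cluster_id", "comparison", "mark", "R", "p_fdr")])
#>   cluster_id   comparison     mark         R        p_fdr
#> 1      G0001 ct01_vs_ct02 H3K36me3 0.8187383 0.0152207100
#> 2      G0001 ct01_vs_ct04 H3K36me3 0.9581329 0.0005536401
#> 3      G0001 ct02_vs_ct03 H3K36me3 0.9008268 0.0032088553
#> 4      G0001 ct03_vs_ct04 H3K36me3 0.9744390 0.0003001113
#> 5      G0002 ct01_vs_ct02 H3K36me3 0.8568216 0.0085345039
#> 8      G0002 ct03_vs_ct04 H3K36me3 0.9079243 0.0028888276

score_recovery(res$calls, study$truth, enrichment = res$enrichment)[c("recall", "precision", "term_rank")]
#> $recall    [1] 1
#> $precision [1] 1
#> $term_rank [1] 1
```

Gene `G0001` is called epispliced for H3K36me3 in four comparisons: its
exon-usage changes and the flank M-values rise and fall together
(R up to 0.97), and every planted epispliced gene is recovered with no
false calls; the planted term ranks first in the enrichment table.

Real studies swap the simulated inputs for file paths (GTF annotation,
bin-by-sample count TSV, a directory of `<cell>_<mark>_rep<i>.bed` peak
files, metadata and term-map TSVs) in `pipeline_config()`, or drive
everything from a YAML file via `read_pipeline_config()`. A thin shell
wrapper lives at `inst/scripts/episplice.R`
(`Rscript episplice.R run-all --config cfg.yaml --seed 1 --out outdir`).
The methods vignette (`vignettes/episplicing-methods.Rmd`) documents the
model, thresholds, numerical choices and the generator's scope.

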