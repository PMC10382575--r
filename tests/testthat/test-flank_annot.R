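# Assignment of differential-peak records to exon flanks and the two-flank
# reduction.

mk_flanks <- function(df) {
  gr <- GRanges(df$contig, IRanges(df$start, df$end))
  mcols(gr) <- S4Vectors::DataFrame(cluster_id = df$cluster_id,
                                    bin_index = df$bin_index, side = df$side)
  gr
}

mk_dhm <- function(start, end, M, p_raw, contig = "chr1",
                   comparison = "A_vs_B", mark = "H3K36me3") {
  data.frame(contig = contig, start = start, end = end, M = M, A = 6,
             p_raw = p_raw, p_fdr = NA, is_dhm = NA,
             comparison = comparison, mark = mark, stringsAsFactors = FALSE)
}

test_that("peaks attach to flanks by >=1 bp overlap, half-open at the BED face", {
  # flank [800,1000) and peak [950,1050): 1-based 801..1000 vs 951..1050
  fl <- mk_flanks(data.frame(contig = "chr1", start = 801, end = 1000,
                             cluster_id = "G", bin_index = 2,
                             side = "upstream"))
  hit <- annotate_flanks(fl, mk_dhm(951, 1050, 1.5, 1e-4))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$M, 1.5)

  # peak [1000,1100) in half-open coordinates starts at 1-based 1001: no overlap
  miss <- annotate_flanks(fl, mk_dhm(1001, 1100, 1.5, 1e-4))
  expect_equal(nrow(miss), 0L)
})

test_that("the most significant peak per flank wins, with deterministic ties", {
  fl <- mk_flanks(data.frame(contig = "chr1", start = 801, end = 1000,
                             cluster_id = "G", bin_index = 2,
                             side = "upstream"))
  two <- rbind(mk_dhm(810, 900, 0.5, 1e-3), mk_dhm(901, 990, 2.5, 1e-8))
  best <- annotate_flanks(fl, two)
  expect_equal(nrow(best), 1L)
  expect_equal(best$p_raw, 1e-8)
  # tie on p: larger |M| wins
  tie <- rbind(mk_dhm(810, 900, -3.1, 1e-5), mk_dhm(901, 990, 2.5, 1e-5))
  expect_equal(annotate_flanks(fl, tie)$M, -3.1)
})

test_that("peak contigs absent from the annotation are skipped with a warning", {
  fl <- mk_flanks(data.frame(contig = "chr1", start = 801, end = 1000,
                             cluster_id = "G", bin_index = 2,
                             side = "upstream"))
  expect_warning(res <- annotate_flanks(fl, mk_dhm(801, 900, 1, 1e-4,
                                                   contig = "chrUn")),
                 "absent")
  expect_equal(nrow(res), 0L)
})

test_that("assignment matches the all-pairs overlap oracle on random input", {
  set.seed(411)
  for (rep in 1:20) {
    nf <- sample(5:40, 1)
    np <- sample(5:40, 1)
    fdf <- data.frame(contig = sample(c("chr1", "chr2"), nf, TRUE),
                      start = sample(1:2000, nf), cluster_id = "G",
                      bin_index = seq_len(nf),
                      side = sample(c("upstream", "downstream"), nf, TRUE))
    fdf$end <- fdf$start + sample(20:200, nf, TRUE)
    pdf <- data.frame(contig = sample(c("chr1", "chr2"), np, TRUE),
                      start = sample(1:2000, np))
    pdf$end <- pdf$start + sample(20:200, np, TRUE)
    dhm <- mk_dhm(pdf$start, pdf$end, rnorm(np), runif(np),
                  contig = pdf$contig)
    got <- suppressWarnings(annotate_flanks(mk_flanks(fdf), dhm))
    want <- oracle_overlap_pairs(fdf, pdf)
    flanks_hit <- if (is.null(want)) integer() else sort(unique(want[, 1]))
    expect_setequal(got$bin_index, fdf$bin_index[flanks_hit])
    # and row-order invariance of the input records
    perm <- sample(np)
    got2 <- suppressWarnings(annotate_flanks(mk_flanks(fdf), dhm[perm, ]))
    expect_equal(got2[order(got2$bin_index), c("bin_index", "M", "p_raw")],
                 got[order(got$bin_index), c("bin_index", "M", "p_raw")],
                 ignore_attr = TRUE)
  }
})

test_that("FDR pooling runs per mark across all comparisons", {
  fl <- mk_flanks(data.frame(contig = "chr1", start = c(801, 2801),
                             end = c(1000, 3000), cluster_id = "G",
                             bin_index = c(2, 3), side = "upstream"))
  d <- rbind(mk_dhm(810, 900, 2, 0.01, comparison = "A_vs_B"),
             mk_dhm(2810, 2900, 2, 0.02, comparison = "A_vs_C"),
             mk_dhm(810, 900, 2, 0.03, comparison = "A_vs_C",
                    mark = "H3K27ac"))
  res <- annotate_flanks(fl, d)
  k36 <- res[res$mark == "H3K36me3", ]
  expect_equal(sort(k36$p_fdr), p.adjust(c(0.01, 0.02), "BH"))
  expect_equal(res$p_fdr[res$mark == "H3K27ac"], 0.03)
})

test_that("two flank signals reduce to one signed exon M-value", {
  fs <- data.frame(cluster_id = "G", bin_index = 2,
                   side = c("upstream", "downstream"),
                   comparison = "A_vs_B", mark = "H3K36me3",
                   M = c(2.1, -0.3), p_raw = c(1e-6, 0.2),
                   p_fdr = c(1e-5, 0.4), significant = c(TRUE, FALSE))
  expect_equal(reduce_to_exon_signal(fs)$M_exon, 2.1)

  none <- transform(fs, significant = FALSE)
  expect_equal(nrow(reduce_to_exon_signal(none)), 0L)

  tie <- transform(fs, significant = TRUE, p_raw = 1e-6, p_fdr = 1e-5,
                   M = c(1.2, 1.8))
  expect_equal(reduce_to_exon_signal(tie)$M_exon, 1.8)
  expect_equal(reduce_to_exon_signal(tie, policy = "mean")$M_exon, 1.5)
  expect_equal(reduce_to_exon_signal(fs, policy = "max-abs-M")$M_exon, 2.1)
  expect_error(reduce_to_exon_signal(fs, policy = "best"), "arg")
})

test_that("grid completion emits every retained exon once, zeros included", {
  ex <- data.frame(contig = "chr1", start = c(1001, 2001, 3001),
                   end = c(1100, 2100, 3100), strand = "+", gene_id = "G",
                   transcript_id = "T1")
  model <- flatten_gene_models(ex)
  fs <- data.frame(cluster_id = "G", bin_index = 2, side = "upstream",
                   comparison = c("A_vs_B", "A_vs_C"), mark = "H3K36me3",
                   M = c(1.5, 0.8), p_raw = c(1e-6, 0.3),
                   p_fdr = c(1e-5, 0.5), significant = c(TRUE, FALSE))
  out <- reduce_to_exon_signal(fs, model = model)
  # 2 non-first bins x 2 comparisons x 1 mark
  expect_equal(nrow(out), 4L)
  expect_equal(sum(out$M_exon != 0), 1L)
  expect_equal(out$M_exon[out$bin_index == 2 & out$comparison == "A_vs_B"],
               1.5)
})
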