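# Flattening, gene-cluster filters and exon flanks.

test_that("overlapping transcript exons are split at every boundary", {
  ex <- data.frame(contig = "chr1",
                   start = c(101, 301, 101, 301), end = c(200, 400, 250, 400),
                   strand = "+", gene_id = "G",
                   transcript_id = rep(c("T1", "T2"), each = 2))
  m <- flatten_gene_models(ex)
  b <- as.data.frame(m$bins)
  expect_equal(b$start, c(101, 201, 301))
  expect_equal(b$end, c(200, 250, 400))
  expect_equal(b$bin_index, 1:3)
  # both leading bins overlap a transcript's 5'-most exon
  expect_equal(b$is_first_exon, c(TRUE, TRUE, FALSE))
})

test_that("single transcript and duplicated transcripts flatten to their exons", {
  ex1 <- data.frame(contig = "chr1", start = c(11, 31), end = c(20, 40),
                    strand = "+", gene_id = "G", transcript_id = "T1")
  m1 <- flatten_gene_models(ex1)
  expect_equal(start(m1$bins), c(11, 31))
  expect_equal(end(m1$bins), c(20, 40))
  expect_equal(mcols(m1$bins)$is_first_exon, c(TRUE, FALSE))

  ex2 <- rbind(ex1, transform(ex1, transcript_id = "T2"))
  m2 <- flatten_gene_models(ex2)
  expect_equal(as.data.frame(m2$bins), as.data.frame(m1$bins))
})

test_that("flattening matches the base-level oracle on random gene models", {
  set.seed(401)
  for (rep in 1:40) {
    ex <- random_gene_model()
    got <- as.data.frame(flatten_gene_models(ex)$bins)
    want <- oracle_flatten_gene(ex)
    expect_equal(got$start, want$start, info = paste("rep", rep))
    expect_equal(got$end, want$end, info = paste("rep", rep))
  }
})

test_that("flattening an already-flattened model is a no-op", {
  set.seed(402)
  for (rep in 1:10) {
    ex <- random_gene_model()
    b1 <- as.data.frame(flatten_gene_models(ex)$bins)
    flat_as_tx <- data.frame(contig = "chr1", start = b1$start, end = b1$end,
                             strand = "+", gene_id = "G",
                             transcript_id = "T1")
    b2 <- as.data.frame(flatten_gene_models(flat_as_tx)$bins)
    expect_equal(b2$start, b1$start)
    expect_equal(b2$end, b1$end)
  }
})

test_that("gene-cluster filters remove each decoy class", {
  ex <- rbind(
    # A and B share exonic sequence
    data.frame(contig = "chr1", start = c(101, 151), end = c(200, 250),
               strand = "+", gene_id = c("A", "B"),
               transcript_id = c("A.T1", "B.T1")),
    # C: same id at two loci on one contig
    data.frame(contig = "chr1", start = c(1001, 1201, 50001, 50201),
               end = c(1100, 1300, 50100, 50300), strand = "+",
               gene_id = "C", transcript_id = rep(c("C.T1", "C.T2"), each = 2)),
    # D: bins on two contigs
    data.frame(contig = c("chr1", "chr2"), start = c(2001, 101),
               end = c(2100, 200), strand = "+", gene_id = "D",
               transcript_id = c("D.T1", "D.T2")),
    # E: single exon
    data.frame(contig = "chr1", start = 3001, end = 3100, strand = "+",
               gene_id = "E", transcript_id = "E.T1"),
    # F: ordinary two-exon gene, retained
    data.frame(contig = "chr1", start = c(4001, 4501), end = c(4100, 4600),
               strand = "+", gene_id = "F", transcript_id = "F.T1"))
  res <- filter_gene_clusters(flatten_gene_models(ex))
  expect_equal(unname(res$report$removed),
               c(2L, 1L, 1L, 1L))  # overlap pair, duplicated, multi-region, single-exon
  expect_equal(res$report$input, 6L)
  expect_equal(res$report$retained, 1L)
  expect_equal(unique(mcols(res$model$bins)$cluster_id), "F")
  expect_equal(res$report$input - res$report$retained,
               sum(res$report$removed))
})

test_that("flanks are intronic, width-clipped, and absent for first exons", {
  ex <- data.frame(contig = "chr1", start = c(1001, 2001), end = c(1500, 2400),
                   strand = "+", gene_id = "G", transcript_id = "T1")
  model <- flatten_gene_models(ex)
  fl <- compute_flanks(model, width = 200)
  # only the non-first bin [2001, 2400] owns flanks
  expect_equal(length(fl), 2L)
  df <- as.data.frame(fl)
  up <- df[df$side == "upstream", ]
  dn <- df[df$side == "downstream", ]
  expect_equal(c(up$start, up$end), c(1801, 2000))
  expect_equal(c(dn$start, dn$end), c(2401, 2600))

  # clipping at the contig origin
  ex2 <- data.frame(contig = "chr1", start = c(51, 1001), end = c(300, 1100),
                    strand = "-", gene_id = "G2", transcript_id = "T1")
  m2 <- flatten_gene_models(ex2)   # minus strand: first exon is bin 2
  fl2 <- compute_flanks(m2, width = 200)
  up2 <- as.data.frame(fl2)[as.data.frame(fl2)$side == "upstream", ]
  expect_equal(c(up2$start, up2$end), c(1, 50))

  expect_error(compute_flanks(model, width = 0), "positive")
  expect_error(compute_flanks(model, width = -5), "positive")
})

test_that("flank count equals twice the non-first bins minus fully clipped", {
  set.seed(403)
  st <- simulate_dataset(simulation_params(n_genes = 40, n_epispliced = 4,
                                           n_deu_only = 2, n_dhm_only = 2,
                                           seed = 403))
  model <- st$model
  fl <- compute_flanks(model)
  n_nonfirst <- sum(!mcols(model$bins)$is_first_exon)
  expect_equal(length(fl), 2L * n_nonfirst)  # no gene close enough to base 1
  expect_true(all(table(paste(mcols(fl)$cluster_id, mcols(fl)$bin_index)) == 2))
})
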