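# Comparison enumeration, ubiquity/pooled filters, Jaccard similarity,
# clustering and the adjusted Rand index.

test_that("19 cell types yield 171 pairwise comparisons", {
  cmp <- enumerate_comparisons(paste0("ct", 1:19))
  expect_equal(nrow(cmp), 171L)
  expect_equal(nrow(cmp), choose(19, 2))
  expect_false(any(duplicated(cmp$comparison)))
  expect_error(enumerate_comparisons("one"), "at least two")
})

test_that("the ubiquity filter keeps exons significant in 1..max_count comparisons", {
  mk <- function(count, total = 171) {
    p <- c(rep(1e-6, count), rep(0.5, total - count))
    data.frame(comparison = paste0("c", seq_len(total)), cell_a = "x",
               cell_b = "y", cluster_id = "G", bin_index = 1,
               deu_value = 1, p_raw = p, p_fdr = p, significant = NA)
  }
  tab3 <- mk(3); tab3$cluster_id <- "G3"
  tab30 <- mk(30); tab30$cluster_id <- "G30"
  tab0 <- mk(0); tab0$cluster_id <- "G0"
  res <- ubiquity_filter(rbind(tab3, tab30, tab0))
  expect_equal(res$genes, "G3")
  ex <- res$exons
  expect_equal(ex$count[ex$cluster_id == "G30"], 30L)
  expect_false(ex$retained[ex$cluster_id == "G30"])
  expect_false(ex$retained[ex$cluster_id == "G0"])
})

test_that("the pooled one-vs-rest filter keeps the shifted exon", {
  set.seed(415)
  st <- simulate_dataset(simulation_params(
    n_cell_types = 4, n_genes = 60, n_epispliced = 0, n_deu_only = 6,
    n_dhm_only = 0, frac_overlapping = 0, frac_duplicated = 0,
    frac_multi_region = 0, frac_single_exon = 0, dirichlet_conc = 1e6,
    seed = 415))
  pf <- pooled_filter(st$counts, st$samples, model = st$model)
  planted_keys <- paste0(st$truth$deu_exons$gene_id, ":",
                         st$truth$deu_exons$bin_index)
  expect_gte(mean(planted_keys %in% pf$keys), 0.8)
  # retained set is a subset of the tested exons
  expect_true(all(pf$keys %in%
                    paste0(pf$exons$cluster_id, ":", pf$exons$bin_index)))
  expect_error(pooled_filter(st$counts,
                             transform(st$samples,
                                       cell_type = rep(c("a", "b"), 4))[1:8, ],
                             model = st$model),
               "3 cell types")
})

test_that("Jaccard index matches its definition and edge cases", {
  expect_equal(jaccard_index(paste0("g", 1:628), paste0("g", 1:1292)),
               628 / 1292)
  expect_equal(round(jaccard_index(paste0("g", 1:628),
                                   paste0("g", 1:1292)), 3), 0.486)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 0)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
               C = character(0))
  J <- jaccard_similarity(sets)$sets
  expect_true(isSymmetric(J))
  expect_equal(diag(J), c(A = 1, B = 1, C = 0))  # empty set: J(0,0) = 0
  expect_equal(J["A", "B"], 2 / 4)
})

test_that("1 - J satisfies the triangle inequality on sampled triples", {
  set.seed(416)
  universe <- paste0("g", 1:40)
  for (rep in 1:30) {
    s <- replicate(3, sample(universe, sample(0:25, 1)), simplify = FALSE)
    d12 <- 1 - jaccard_index(s[[1]], s[[2]])
    d13 <- 1 - jaccard_index(s[[1]], s[[3]])
    d23 <- 1 - jaccard_index(s[[2]], s[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("ARI matches the pair-enumeration oracle and is properly adjusted", {
  set.seed(417)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y),
                 tolerance = 1e-12)
    # symmetry and label-renaming invariance
    expect_equal(adjusted_rand_index(y, x), adjusted_rand_index(x, y))
    relab <- c(7, 5, 9)[x]
    expect_equal(adjusted_rand_index(relab, y), adjusted_rand_index(x, y))
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # a single cluster against an informative labeling adjusts to 0
  expect_equal(adjusted_rand_index(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
})

test_that("ARI agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(418)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("planted cell-type groups are recovered with ARI 1", {
  sim <- simulate_epispliced_catalog(seed = 419)
  J <- jaccard_similarity(sim$sets)$sets
  within <- J[1:3, 1:3][upper.tri(J[1:3, 1:3])]
  between <- J[1:3, 4:6]
  expect_true(all(within >= 0.4))
  expect_true(all(between <= 0.05))
  meta <- data.frame(cell_type = names(sim$sets), group = unname(sim$groups))
  cs <- cluster_and_score(J, meta, schemes = "group")
  expect_equal(cs$ari, 1)
})

test_that("single-label schemes report NA", {
  sets <- list(A = c("g1"), B = c("g1"), C = c("g2"))
  J <- jaccard_similarity(sets)$sets
  meta <- data.frame(cell_type = c("A", "B", "C"), flat = "same")
  cs <- cluster_and_score(J, meta, schemes = "flat")
  expect_true(is.na(cs$ari))
})
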