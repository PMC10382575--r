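# Odds-ratio co-occurrence and per-gene DEU-DHM correlation.

test_that("odds ratio, CI and Fisher p behave on canonical tables", {
  r <- contingency_odds_ratio(1, 1, 1, 1)
  expect_equal(r$or, 1)
  expect_equal(r$p_fet, 1)

  # all-zero-free Haldane path
  h <- contingency_odds_ratio(0, 5, 5, 5)
  expect_true(h$corrected)
  expect_equal(h$or, (0.5 * 5.5) / (5.5 * 5.5))

  expect_error(contingency_odds_ratio(0, 0, 0, 0), "empty")
  expect_error(contingency_odds_ratio(-1, 1, 1, 1), "non-negative")
})

test_that("transposition fixes OR; swapping DHM rows inverts it", {
  set.seed(412)
  for (rep in 1:10) {
    n <- sample(1:50, 4)
    a <- contingency_odds_ratio(n[1], n[2], n[3], n[4])
    # transpose: swap the two off-diagonal cells
    b <- contingency_odds_ratio(n[1], n[3], n[2], n[4])
    expect_equal(a$or, b$or)
    # swap DHM rows: (n00,n10) <-> (n01,n11)
    c <- contingency_odds_ratio(n[3], n[4], n[1], n[2])
    expect_equal(c$or, 1 / a$or, tolerance = 1e-12)
    expect_equal(c$p_fet, a$p_fet, tolerance = 1e-9)
  }
})

test_that("Fisher p equals hypergeometric enumeration on small tables", {
  set.seed(413)
  for (rep in 1:50) {
    repeat {
      n <- sample(0:15, 4, replace = TRUE)
      if (sum(n) > 0 && sum(n) <= 40) break
    }
    got <- contingency_odds_ratio(n[1], n[2], n[3], n[4])$p_fet
    expect_equal(got, oracle_fisher_p(n[1], n[2], n[3], n[4]),
                 tolerance = 1e-9, info = paste(n, collapse = ","))
  }
})

test_that("grouped association: identical profiles, Haldane cells, partition consistency", {
  flags <- data.frame(
    cluster_id = rep(c("G1", "G2"), each = 4),
    bin_index = rep(1:4, 2),
    deu = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
    dhm = rep(c(TRUE, TRUE, FALSE, FALSE), 2))
  res <- grouped_association(flags)
  genes <- res[res$scope == "gene", ]
  expect_equal(genes$or[1], genes$or[2])
  # one gene: n11 = 2, n00 = 2, n10 = n01 = 0 -> corrected Haldane OR
  expect_true(all(genes$corrected))
  expect_equal(genes$or[1], (2.5 * 2.5) / (0.5 * 0.5))

  # a term containing every gene reproduces the global table
  tm <- data.frame(gene_id = c("G1", "G2"), term_id = "ALL")
  tr <- grouped_association(flags, grouping = "term", term_map = tm)
  expect_equal(tr$or[tr$scope_id == "ALL"], tr$or[tr$scope_id == "BASELINE"])
  expect_equal(unlist(tr[tr$scope_id == "ALL", c("n00", "n10", "n01", "n11")]),
               unlist(tr[tr$scope_id == "BASELINE",
                         c("n00", "n10", "n01", "n11")]))
})

test_that("exon event flags pool comparisons and marks correctly", {
  deu <- rbind(make_deu_rows("G1", 1:2, c(2, 0), p_raw = c(1e-5, 0.5)),
               make_deu_rows("G1", 1:2, c(0, 0), p_raw = c(0.9, 0.9),
                             comparison = "A_vs_C", cell_b = "C"))
  deu$significant <- deu$p_raw <= 0.05
  fs <- data.frame(cluster_id = "G1", bin_index = 2, side = "upstream",
                   comparison = "A_vs_B",
                   mark = c("H3K36me3", "H3K27ac"),
                   M = 2, p_raw = 1e-6, p_fdr = c(1e-5, 0.9),
                   significant = c(TRUE, FALSE))
  flags <- exon_event_flags(deu, fs)
  k36 <- flags[flags$mark == "H3K36me3", ]
  expect_equal(k36$deu[k36$bin_index == 1], TRUE)
  expect_equal(k36$dhm[k36$bin_index == 2], TRUE)
  expect_equal(k36$dhm[k36$bin_index == 1], FALSE)
  all_marks <- flags[flags$mark == "all", ]
  expect_equal(all_marks$dhm[all_marks$bin_index == 2], TRUE)  # any-mark rule
})

test_that("gene correlation reproduces hand-computed R with its t-test p", {
  deu <- make_deu_rows("G1", 1:4, c(0, 0, 2, 0))
  sig <- make_signal_rows("G1", 1:4, c(0, 0, 1.5, 0))
  r <- gene_deu_dhm_correlation(deu, sig)
  expect_equal(r$R, 1)

  deu2 <- make_deu_rows("G1", 1:3, c(0, 1, 2))
  sig2 <- make_signal_rows("G1", 1:3, c(2, 1, 0))
  expect_equal(gene_deu_dhm_correlation(deu2, sig2)$R, -1)

  x <- c(1.2, 0, -0.8, 0.1)
  y <- c(2.0, 0, -1.5, 0.4)
  r3 <- gene_deu_dhm_correlation(make_deu_rows("G1", 1:4, x),
                                 make_signal_rows("G1", 1:4, y))
  # independent summation formula
  n <- 4
  rr <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(r3$R, rr, tolerance = 1e-12)
  tt <- rr * sqrt((n - 2) / (1 - rr^2))
  expect_equal(r3$p_raw, 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
})

test_that("the rank-correlation alternative is available", {
  x <- c(0.1, 1, 2, 4, 8.5)
  y <- c(0.2, 1.5, 2.1, 5, 30)   # monotone but non-linear
  r <- gene_deu_dhm_correlation(make_deu_rows("G", 1:5, x),
                                make_signal_rows("G", 1:5, y),
                                method = "spearman")
  expect_equal(r$R, 1)
})

test_that("R is affine-invariant and sign-flips under negation", {
  set.seed(414)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    base <- gene_deu_dhm_correlation(make_deu_rows("G", 1:6, x),
                                     make_signal_rows("G", 1:6, y))$R
    resc <- gene_deu_dhm_correlation(make_deu_rows("G", 1:6, 3 * x + 0),
                                     make_signal_rows("G", 1:6, 0.5 * y))$R
    expect_equal(resc, base, tolerance = 1e-10)
    neg <- gene_deu_dhm_correlation(make_deu_rows("G", 1:6, x),
                                    make_signal_rows("G", 1:6, -y))$R
    expect_equal(neg, -base, tolerance = 1e-10)
  }
})

test_that("degenerate correlation inputs are excluded", {
  # fewer than 3 exons
  short <- gene_deu_dhm_correlation(make_deu_rows("G", 1:2, c(1, 2)),
                                    make_signal_rows("G", 1:2, c(1, 2)))
  expect_equal(nrow(short), 0L)
  # zero variance
  flat <- gene_deu_dhm_correlation(make_deu_rows("G", 1:4, c(0, 0, 0, 0)),
                                   make_signal_rows("G", 1:4, c(1, 2, 3, 4)))
  expect_equal(nrow(flat), 0L)
})

test_that("epispliced calls require both |R| and FDR thresholds", {
  co <- data.frame(cluster_id = c("G1", "G2", "G3"),
                   comparison = "A_vs_B", cell_a = "A", cell_b = "B",
                   mark = "H3K36me3", R = c(-0.84, 0.45, 0.9),
                   n_exons = 10, p_raw = c(1e-4, 1e-5, 0.1),
                   p_fdr = c(0.01, 0.001, 0.2))
  calls <- call_epispliced(co)
  expect_equal(calls$is_epispliced, c(TRUE, FALSE, FALSE))
  expect_equal(calls$direction[1], -1)
})

test_that("a call counts for both cell types of its comparison", {
  co <- data.frame(cluster_id = "G1", comparison = "A_vs_B",
                   cell_a = "A", cell_b = "B", mark = "H3K36me3",
                   R = 0.9, n_exons = 10, p_raw = 1e-6, p_fdr = 1e-4)
  cat <- epispliced_catalog(call_epispliced(co), cell_types = c("A", "B", "C"))
  expect_equal(cat$H3K36me3$A, "G1")
  expect_equal(cat$H3K36me3$B, "G1")
  expect_equal(cat$H3K36me3$C, character(0))
})
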