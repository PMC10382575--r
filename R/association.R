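# DEU-DHM co-occurrence: odds ratios with Fisher exact tests (global,
# per gene, per term group) and per-gene correlation between DEU values and
# flank M-values, from which epispliced genes are called.

#' Odds ratio, Woolf confidence interval and Fisher test for a 2x2 table
#'
#' The contingency cells follow the event-overlap layout
#' \describe{
#'   \item{n00}{exons with neither DEU nor DHM}
#'   \item{n10}{exons with DEU only}
#'   \item{n01}{exons with DHM only}
#'   \item{n11}{exons with both}
#' }
#' and the odds ratio is \eqn{OR = (n_{00} n_{11}) / (n_{10} n_{01})}: values
#' above 1 mean differential usage is more likely where the mark changes.
#' If any cell is zero, 0.5 is added to all four cells (Haldane-Anscombe)
#' for the OR and CI, flagged in the result; the Fisher p-value is always
#' computed on the original integer cells.  The 95% CI uses the Woolf logit
#' interval \eqn{\exp(\ln OR \pm 1.96\sqrt{\sum 1/n_{ij}})}.
#'
#' @param n00,n10,n01,n11 non-negative integer cell counts; alternatively
#'   pass a 2x2 matrix `rbind(c(n00, n10), c(n01, n11))` as `n00`.
#' @return one-row data frame: `n00, n10, n01, n11, or, ci_low, ci_high,
#'   p_fet, corrected`.
#' @examples
#' contingency_odds_ratio(8198, 5149, 34585, 79888)  # OR 3.68 [3.54, 3.82]
#' @export
contingency_odds_ratio <- function(n00, n10 = NULL, n01 = NULL, n11 = NULL) {
  if (is.matrix(n00)) {
    stopifnot(all(dim(n00) == 2L))
    n11 <- n00[2L, 2L]; n01 <- n00[2L, 1L]; n10 <- n00[1L, 2L]
    n00 <- n00[1L, 1L]
  }
  cells <- c(n00, n10, n01, n11)
  if (any(is.na(cells)) || any(cells < 0)) stop("cells must be non-negative")
  if (sum(cells) == 0) stop("empty contingency table")
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1L] * cc[4L]) / (cc[2L] * cc[3L])
  se <- sqrt(sum(1 / cc))
  p <- fisher.test(matrix(cells, nrow = 2L, byrow = TRUE))$p.value
  data.frame(n00 = n00, n10 = n10, n01 = n01, n11 = n11,
             or = or,
             ci_low = exp(log(or) - 1.96 * se),
             ci_high = exp(log(or) + 1.96 * se),
             p_fet = p, corrected = corrected)
}

#' Build per-exon DEU/DHM event flags
#'
#' Reduces a DEU table (with significance flags set) and a flank-signal
#' table to one row per exon bin and mark with logical `deu` / `dhm` event
#' indicators.  In the default `"pooled"` unit an exon is DEU-flagged when
#' significant in at least one considered comparison and DHM-flagged when at
#' least one of its flank records for the mark is significant; the
#' `"per-comparison"` unit keeps exon-by-comparison rows.  Rows for
#' `mark = "all"` pool the five marks with an any-mark DHM flag.
#'
#' @param deu_table `DeuTable` after [apply_deu_significance()].
#' @param flank_signals `FlankSignalTable` from [annotate_flanks()].
#' @param unit `"pooled"` (default) or `"per-comparison"`.
#' @param add_all also emit the pooled-over-marks `"all"` rows (default TRUE).
#' @return data frame: `mark, comparison (unit-dependent), cluster_id,
#'   bin_index, deu, dhm`.
#' @export
exon_event_flags <- function(deu_table, flank_signals,
                             unit = c("pooled", "per-comparison"),
                             add_all = TRUE) {
  unit <- match.arg(unit)
  marks <- unique(flank_signals$mark)
  if (add_all && length(marks) > 1L) marks <- c(marks, "all")
  scope <- unique(deu_table[, c("cluster_id", "bin_index")])
  out <- list()
  for (m in marks) {
    fs <- if (m == "all") flank_signals else
      flank_signals[flank_signals$mark == m, , drop = FALSE]
    if (unit == "pooled") {
      deu_keys <- unique(bin_key(deu_table$cluster_id,
                                 deu_table$bin_index)[deu_table$significant %in% TRUE])
      dhm_keys <- unique(bin_key(fs$cluster_id,
                                 fs$bin_index)[fs$significant %in% TRUE])
      keys <- bin_key(scope$cluster_id, scope$bin_index)
      out[[m]] <- data.frame(mark = m, comparison = "pooled",
                             cluster_id = scope$cluster_id,
                             bin_index = scope$bin_index,
                             deu = keys %in% deu_keys,
                             dhm = keys %in% dhm_keys,
                             stringsAsFactors = FALSE)
    } else {
      deu_keys <- unique(paste(deu_table$comparison,
                               bin_key(deu_table$cluster_id, deu_table$bin_index),
                               sep = "\r")[deu_table$significant %in% TRUE])
      dhm_keys <- unique(paste(fs$comparison,
                               bin_key(fs$cluster_id, fs$bin_index),
                               sep = "\r")[fs$significant %in% TRUE])
      grid <- unique(deu_table[, c("comparison", "cluster_id", "bin_index")])
      keys <- paste(grid$comparison,
                    bin_key(grid$cluster_id, grid$bin_index), sep = "\r")
      out[[m]] <- data.frame(mark = m, comparison = grid$comparison,
                             cluster_id = grid$cluster_id,
                             bin_index = grid$bin_index,
                             deu = keys %in% deu_keys,
                             dhm = keys %in% dhm_keys,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

or_from_flags <- function(deu, dhm) {
  contingency_odds_ratio(sum(!deu & !dhm), sum(deu & !dhm),
                         sum(!deu & dhm), sum(deu & dhm))
}

#' Grouped odds-ratio association analysis
#'
#' Computes one contingency table and [contingency_odds_ratio()] result per
#' group of exons (per gene, or per term via a gene-to-term map), plus a
#' `BASELINE` row over all exons in scope.  Fisher p-values are
#' Benjamini-Hochberg adjusted across groups (the baseline row is not part
#' of the adjustment pool) and `significant = (or >= 1 & p_fdr <= 0.05)`.
#'
#' @param flags one mark's rows from [exon_event_flags()] (columns
#'   `cluster_id, bin_index, deu, dhm`).
#' @param grouping `"gene"` (default) or `"term"`.
#' @param term_map for `grouping = "term"`: data frame `gene_id, term_id`
#'   (optionally pre-filtered to one ontology level).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return `AssociationResults` data frame: `scope, scope_id, n00, n10, n01,
#'   n11, or, ci_low, ci_high, p_fet, p_fdr, significant`.
#' @export
grouped_association <- function(flags, grouping = c("gene", "term"),
                                term_map = NULL, alpha = 0.05) {
  grouping <- match.arg(grouping)
  stopifnot(all(c("cluster_id", "deu", "dhm") %in% names(flags)))
  groups <- if (grouping == "gene") {
    split(seq_len(nrow(flags)), flags$cluster_id)
  } else {
    stopifnot(!is.null(term_map),
              all(c("gene_id", "term_id") %in% names(term_map)))
    lapply(split(term_map$gene_id, term_map$term_id),
           function(gs) which(flags$cluster_id %in% gs))
  }
  empty <- vapply(groups, length, integer(1)) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty group(s): ",
            paste(head(names(groups)[empty], 5L), collapse = ", "))
    groups <- groups[!empty]
  }
  rows <- lapply(names(groups), function(g) {
    r <- or_from_flags(flags$deu[groups[[g]]], flags$dhm[groups[[g]]])
    cbind(data.frame(scope = grouping, scope_id = g,
                     stringsAsFactors = FALSE), r)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_adjust(res$p_fet)
  res$significant <- res$or >= 1 & res$p_fdr <= alpha
  base <- cbind(data.frame(scope = "global", scope_id = "BASELINE",
                           stringsAsFactors = FALSE),
                or_from_flags(flags$deu, flags$dhm))
  base$p_fdr <- NA_real_
  base$significant <- NA
  res <- rbind(base, res)
  rownames(res) <- NULL
  res
}

#' Per-gene correlation between DEU values and exon M-values
#'
#' For each (gene, comparison, mark), pairs the gene's per-exon DEU values
#' (zeroing rule already applied via [apply_deu_significance()]) with the
#' exon M-values (zero where no significant flank signal;
#' [reduce_to_exon_signal()]) and computes the Pearson (or Spearman)
#' correlation R over the gene's retained non-first-exon bins.  Genes with
#' fewer than 3 paired exons or a zero-variance vector are excluded.  Raw
#' p-values come from the t-transform
#' \eqn{t = R\sqrt{(n-2)/(1-R^2)}}; the Benjamini-Hochberg correction pools
#' all (gene, comparison, mark) tests.
#'
#' @param deu_table zeroed `DeuTable` (all comparisons).
#' @param exon_signals completed `ExonSignalTable`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return `GeneCorrelations` data frame: `cluster_id, comparison, cell_a,
#'   cell_b, mark, R, n_exons, p_raw, p_fdr`.
#' @export
gene_deu_dhm_correlation <- function(deu_table, exon_signals,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  d <- deu_table[!is.na(deu_table$deu_value), , drop = FALSE]
  merged <- merge(d[, c("comparison", "cell_a", "cell_b", "cluster_id",
                        "bin_index", "deu_value")],
                  exon_signals,
                  by = c("comparison", "cluster_id", "bin_index"))
  if (nrow(merged) == 0L) {
    if (nrow(d) > 0L && nrow(exon_signals) > 0L)
      stop("DEU table and exon-signal table share no (gene, bin, comparison) rows; ",
           "check that both derive from the same flattened model")
    return(data.frame(cluster_id = character(), comparison = character(),
                      cell_a = character(), cell_b = character(),
                      mark = character(), R = numeric(), n_exons = integer(),
                      p_raw = numeric(), p_fdr = numeric()))
  }
  key <- paste(merged$cluster_id, merged$comparison, merged$mark, sep = "\r")
  idx <- split(seq_len(nrow(merged)), key)
  rows <- lapply(idx, function(i) {
    x <- merged$deu_value[i]
    y <- merged$M_exon[i]
    n <- length(x)
    if (n < 3L || sd(x) == 0 || sd(y) == 0) return(NULL)
    r <- cor(x, y, method = method)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(cluster_id = merged$cluster_id[i[1L]],
               comparison = merged$comparison[i[1L]],
               cell_a = merged$cell_a[i[1L]],
               cell_b = merged$cell_b[i[1L]],
               mark = merged$mark[i[1L]],
               R = r, n_exons = n,
               p_raw = 2 * pt(-abs(tt), df = n - 2),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(cluster_id = character(), comparison = character(),
                      cell_a = character(), cell_b = character(),
                      mark = character(), R = numeric(), n_exons = integer(),
                      p_raw = numeric(), p_fdr = numeric()))
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

#' Call epispliced genes from gene correlations
#'
#' A gene is epispliced in a (comparison, mark) when `|R| >= r_min` and the
#' FDR-adjusted p is at most `alpha`; the sign of R is retained as the call
#' direction (correlated vs anti-correlated).
#'
#' @param correlations `GeneCorrelations` from [gene_deu_dhm_correlation()].
#' @param r_min minimum absolute correlation (default 0.5).
#' @param alpha FDR threshold (default 0.05).
#' @return the table with `is_epispliced` and `direction` columns added.
#' @export
call_epispliced <- function(correlations, r_min = 0.5, alpha = 0.05) {
  stopifnot(r_min >= 0, r_min <= 1, alpha > 0, alpha <= 1)
  correlations$is_epispliced <- abs(correlations$R) >= r_min &
    !is.na(correlations$p_fdr) & correlations$p_fdr <= alpha
  correlations$direction <- sign(correlations$R)
  correlations
}

#' Organize epispliced calls into per-cell-type gene sets
#'
#' A call made in the comparison of cell types A and B counts for both A
#' and B.  Returns, per mark (plus the union `"combined"`), a named list of
#' epispliced gene sets per cell type.
#'
#' @param calls output of [call_epispliced()] with `cell_a`/`cell_b` set.
#' @param cell_types optional full roster so that cell types without calls
#'   appear with empty sets.
#' @return `EpisplicedCatalog`: named list `mark -> cell_type -> character`.
#' @export
epispliced_catalog <- function(calls, cell_types = NULL) {
  hits <- calls[calls$is_epispliced %in% TRUE, , drop = FALSE]
  if (is.null(cell_types)) {
    cell_types <- sort(unique(c(calls$cell_a, calls$cell_b)))
  }
  marks <- sort(unique(calls$mark))
  per_mark <- lapply(marks, function(m) {
    h <- hits[hits$mark == m, , drop = FALSE]
    sets <- lapply(cell_types, function(ct) {
      sort(unique(h$cluster_id[h$cell_a == ct | h$cell_b == ct]))
    })
    names(sets) <- cell_types
    sets
  })
  names(per_mark) <- marks
  if (length(marks) > 1L) {
    per_mark$combined <- lapply(setNames(cell_types, cell_types), function(ct) {
      sort(unique(hits$cluster_id[hits$cell_a == ct | hits$cell_b == ct]))
    })
  }
  structure(per_mark, class = "EpisplicedCatalog")
}

#' @export
print.EpisplicedCatalog <- function(x, ...) {
  for (m in names(x)) {
    cat(m, ": ",
        paste(sprintf("%s=%d", names(x[[m]]),
                      vapply(x[[m]], length, integer(1))), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}
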