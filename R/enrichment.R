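# Hypergeometric over-representation analysis of epispliced gene sets
# against a stated background universe.

#' Term over-representation analysis
#'
#' One-sided hypergeometric test per term: with `N` background genes of
#' which `K` carry the term, and a study set of `n` genes of which `k` carry
#' it, `p_raw = P[X >= k]` for `X ~ Hypergeometric(N, K, n)` and
#' `fold_enrichment = (k/n) / (K/N)`.  Terms without background genes are
#' skipped; p-values are Benjamini-Hochberg adjusted across tested terms.
#' The intended background is the set of all genes carrying either a DEU or
#' a DHM event, so that enrichment reflects episplicing rather than mere
#' detectability.
#'
#' @param gene_set study genes (must be a subset of `background`).
#' @param background background gene universe.
#' @param term_map data frame `gene_id, term_id` (rows for genes outside the
#'   background are ignored).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return `EnrichmentTable` data frame sorted by decreasing fold
#'   enrichment: `term_id, k, n, K, N, fold_enrichment, p_raw, p_fdr,
#'   significant`.
#' @export
term_enrichment <- function(gene_set, background, term_map, alpha = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  gene_set <- unique(gene_set)
  background <- unique(background)
  if (length(gene_set) == 0L) stop("empty gene set")
  outside <- setdiff(gene_set, background)
  if (length(outside) > 0L) {
    stop("gene(s) outside the background universe: ",
         paste(head(outside, 10L), collapse = ", "))
  }
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  if (nrow(tm) == 0L) stop("term map covers no background gene")
  N <- length(background)
  n <- length(gene_set)
  terms <- split(unique(tm)[, "gene_id"], unique(tm)[, "term_id"])
  rows <- lapply(names(terms), function(t) {
    K <- length(terms[[t]])
    k <- length(intersect(terms[[t]], gene_set))
    data.frame(term_id = t, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_raw = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_adjust(res$p_raw)
  res$significant <- res$p_fdr <= alpha
  res <- res[order(-res$fold_enrichment, res$p_raw), ]
  rownames(res) <- NULL
  res
}

#' Enrichment across marks and correlation directions
#'
#' Convenience driver running [term_enrichment()] once per mark, once per
#' correlation direction within each mark (positively vs negatively
#' correlated calls), and once for the union across marks.  Contexts whose
#' gene set is empty (after intersection with the background) are skipped.
#'
#' @param calls epispliced calls ([call_epispliced()] output).
#' @param background background gene universe.
#' @param term_map data frame `gene_id, term_id`.
#' @param alpha FDR threshold (default 0.05).
#' @return data frame of [term_enrichment()] results with `mark` and
#'   `direction` (`"any"`, `"positive"`, `"negative"`) columns prepended.
#' @export
enrichment_by_context <- function(calls, background, term_map,
                                  alpha = 0.05) {
  hits <- calls[calls$is_epispliced %in% TRUE, , drop = FALSE]
  contexts <- list(list(mark = "union", direction = "any"))
  for (m in unique(hits$mark)) {
    contexts <- c(contexts,
                  list(list(mark = m, direction = "any"),
                       list(mark = m, direction = "positive"),
                       list(mark = m, direction = "negative")))
  }
  rows <- lapply(contexts, function(ctx) {
    h <- hits
    if (ctx$mark != "union") h <- h[h$mark == ctx$mark, , drop = FALSE]
    if (ctx$direction == "positive") h <- h[h$direction > 0, , drop = FALSE]
    if (ctx$direction == "negative") h <- h[h$direction < 0, , drop = FALSE]
    genes <- intersect(unique(h$cluster_id), background)
    if (length(genes) == 0L) return(NULL)
    cbind(data.frame(mark = ctx$mark, direction = ctx$direction,
                     stringsAsFactors = FALSE),
          term_enrichment(genes, background, term_map, alpha = alpha))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
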