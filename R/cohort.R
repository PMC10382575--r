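# Cohort-level analysis: comparison enumeration, the non-ubiquity and
# pooled significance filters, Jaccard similarity of epispliced gene sets,
# hierarchical clustering of cell types and adjusted-Rand scoring against
# label schemes.

#' Enumerate all pairwise cell-type comparisons
#'
#' @param cell_types character vector of cell types (>= 2).
#' @return data frame `cell_a, cell_b, comparison` with `choose(n, 2)` rows.
#' @examples
#' nrow(enumerate_comparisons(paste0("ct", 1:19)))  # 171
#' @export
enumerate_comparisons <- function(cell_types) {
  cell_types <- unique(cell_types)
  if (length(cell_types) < 2L) stop("need at least two cell types")
  pairs <- combn(cell_types, 2L)
  data.frame(cell_a = pairs[1L, ], cell_b = pairs[2L, ],
             comparison = comparison_label(pairs[1L, ], pairs[2L, ]),
             stringsAsFactors = FALSE)
}

#' Non-ubiquity filter on pairwise DEU results
#'
#' Counts, per exon, the pairwise comparisons in which its usage change is
#' significant at the strict threshold (`p_fdr <= strict_alpha`).  Exons
#' significant in at least one but at most `max_count` comparisons are
#' retained as "non-ubiquitous"; genes containing at least one such exon
#' form the analysis gene set.  With `mode = "quantile"`, `max_count` is the
#' 95th percentile (configurable via `q`) of the positive-count
#' distribution.
#'
#' @param pairwise_deu `DeuTable` rows concatenated over all comparisons.
#' @param strict_alpha strict FDR threshold (default 1e-4).
#' @param max_count retention ceiling (default 25).
#' @param mode `"fixed"` (default) or `"quantile"`.
#' @param q quantile used in `"quantile"` mode (default 0.95).
#' @return list: `exons` (data frame `cluster_id, bin_index, count,
#'   retained`), `genes` (character), `max_count` (value used).
#' @export
ubiquity_filter <- function(pairwise_deu, strict_alpha = 1e-4,
                            max_count = 25L, mode = c("fixed", "quantile"),
                            q = 0.95) {
  mode <- match.arg(mode)
  key <- bin_key(pairwise_deu$cluster_id, pairwise_deu$bin_index)
  sig <- !is.na(pairwise_deu$p_fdr) & pairwise_deu$p_fdr <= strict_alpha
  counts <- tapply(sig, key, sum)
  uk <- !duplicated(key)
  exons <- data.frame(cluster_id = pairwise_deu$cluster_id[uk],
                      bin_index = pairwise_deu$bin_index[uk],
                      stringsAsFactors = FALSE)
  exons$count <- as.integer(counts[bin_key(exons$cluster_id, exons$bin_index)])
  if (mode == "quantile") {
    pos <- exons$count[exons$count > 0L]
    max_count <- if (length(pos)) as.integer(ceiling(quantile(pos, q))) else 0L
  }
  exons$retained <- exons$count >= 1L & exons$count <= max_count
  list(exons = exons,
       genes = sort(unique(exons$cluster_id[exons$retained])),
       max_count = max_count)
}

#' Pooled one-vs-rest significance filter
#'
#' For each cell type, tests every exon's usage in that cell type against
#' the pooled remainder of the cohort with the built-in usage statistic,
#' then retains exons whose minimum Benjamini-Hochberg-adjusted p over the
#' one-vs-rest analyses is at most `alpha`.  Downstream, pairwise DEU values
#' of exons not retained here are set to zero (see
#' [apply_pooled_filter()]).
#'
#' @param counts bin-by-sample count matrix (all samples, all cell types).
#' @param samples data frame `sample, cell_type`.
#' @param alpha FDR threshold (default 0.05).
#' @param model optional filtered `ExonModel` passed to [test_exon_usage()].
#' @return list: `exons` (data frame `cluster_id, bin_index, min_p_fdr,
#'   retained`), `keys` (retained bin keys).
#' @export
pooled_filter <- function(counts, samples, alpha = 0.05, model = NULL) {
  types <- unique(samples$cell_type)
  if (length(types) < 3L) stop("pooled filter needs at least 3 cell types")
  min_p <- NULL
  for (ct in types) {
    s2 <- samples
    s2$cell_type <- ifelse(samples$cell_type == ct, ct, ".rest")
    res <- test_exon_usage(counts, s2, ".rest", ct, model = model)
    if (is.null(min_p)) {
      min_p <- res[, c("cluster_id", "bin_index")]
      min_p$min_p_fdr <- Inf
    }
    min_p$min_p_fdr <- pmin(min_p$min_p_fdr,
                            ifelse(is.na(res$p_fdr), Inf, res$p_fdr))
  }
  min_p$retained <- min_p$min_p_fdr <= alpha
  list(exons = min_p,
       keys = bin_key(min_p$cluster_id, min_p$bin_index)[min_p$retained])
}

#' Zero pairwise DEU values of exons failing the pooled filter
#'
#' @param deu_table pairwise `DeuTable`.
#' @param retained_keys `keys` element of [pooled_filter()] output.
#' @return the table with non-retained exons' `deu_value` set to 0.
#' @export
apply_pooled_filter <- function(deu_table, retained_keys) {
  drop <- !(bin_key(deu_table$cluster_id, deu_table$bin_index) %in%
              retained_keys)
  deu_table$deu_value[drop & !is.na(deu_table$deu_value)] <- 0
  deu_table$significant[drop] <- FALSE
  deu_table
}

#' Jaccard index of two gene sets
#'
#' \eqn{J(E_1, E_2) = |E_1 \cap E_2| / |E_1 \cup E_2|}; defined as 0 when
#' both sets are empty.
#'
#' @param e1,e2 character vectors.
#' @return numeric in [0, 1].
#' @examples
#' jaccard_index(paste0("g", 1:628), paste0("g", 1:1292))  # 0.486
#' @export
jaccard_index <- function(e1, e2) {
  u <- length(union(e1, e2))
  if (u == 0L) return(0)
  length(intersect(e1, e2)) / u
}

#' Pairwise Jaccard similarity matrices of epispliced gene sets
#'
#' @param catalog an `EpisplicedCatalog` ([epispliced_catalog()]) or a plain
#'   named list of per-cell-type gene sets (treated as a single mark).
#' @return named list of symmetric similarity matrices, one per mark (and
#'   `"combined"` when present in the catalog).
#' @export
jaccard_similarity <- function(catalog) {
  if (!inherits(catalog, "EpisplicedCatalog")) catalog <- list(sets = catalog)
  lapply(catalog, function(sets) {
    cts <- names(sets)
    J <- matrix(0, length(cts), length(cts), dimnames = list(cts, cts))
    for (i in seq_along(cts)) for (j in seq_len(i)) {
      J[i, j] <- J[j, i] <- jaccard_index(sets[[i]], sets[[j]])
    }
    J
  })
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' 1 for identical partitions, about 0 for random ones.
#'
#' @param x,y label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0L)
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / denom
}

#' Cluster cell types by episplicing similarity and score label schemes
#'
#' Hierarchically clusters cell types on the distance `1 - J` (average
#' linkage by default).  For each metadata label scheme the dendrogram is
#' cut at `k` = number of distinct labels and the agreement between the cut
#' and the labels is scored by the adjusted Rand index.  Schemes with a
#' single distinct label are reported with `NA`.
#'
#' @param similarity symmetric Jaccard matrix (one mark).
#' @param metadata data frame with a `cell_type` column and one column per
#'   label scheme.
#' @param schemes scheme column names (default: the four developmental
#'   annotations `potency, sample_type, origin, life_stage`, intersected
#'   with what `metadata` provides).
#' @param linkage `hclust` method (default `"average"`).
#' @return `ClusterScores` data frame `scheme, k, ari`, with attributes
#'   `hclust` (the tree) and `assignments` (cut labels per scheme).
#' @export
cluster_and_score <- function(similarity, metadata,
                              schemes = c("potency", "sample_type",
                                          "origin", "life_stage"),
                              linkage = "average") {
  stopifnot(is.matrix(similarity),
            identical(rownames(similarity), colnames(similarity)),
            "cell_type" %in% names(metadata))
  schemes <- intersect(schemes, names(metadata))
  if (length(schemes) == 0L) stop("no requested scheme column in metadata")
  cts <- rownames(similarity)
  meta <- metadata[match(cts, metadata$cell_type), , drop = FALSE]
  if (anyNA(meta$cell_type)) stop("metadata lacks rows for some cell types")
  hc <- hclust(as.dist(1 - similarity), method = linkage)
  assignments <- list()
  rows <- lapply(schemes, function(sc) {
    labels <- as.character(meta[[sc]])
    k <- length(unique(labels))
    if (k < 2L) {
      assignments[[sc]] <<- rep(1L, length(cts))
      return(data.frame(scheme = sc, k = k, ari = NA_real_))
    }
    cl <- cutree(hc, k = k)
    assignments[[sc]] <<- cl
    data.frame(scheme = sc, k = k, ari = adjusted_rand_index(cl, labels))
  })
  res <- do.call(rbind, rows)
  attr(res, "hclust") <- hc
  attr(res, "assignments") <- assignments
  class(res) <- c("ClusterScores", class(res))
  res
}

#' Write similarity matrices in long form
#' @param sim list of matrices from [jaccard_similarity()].
#' @param path output TSV path.
#' @export
write_similarity <- function(sim, path) {
  rows <- lapply(names(sim), function(m) {
    J <- sim[[m]]
    idx <- which(upper.tri(J, diag = TRUE), arr.ind = TRUE)
    data.frame(mark = m, type_a = rownames(J)[idx[, 1L]],
               type_b = colnames(J)[idx[, 2L]], jaccard = J[idx])
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
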