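# Differential exon usage: a simplified built-in exact test on pooled
# replicate counts, an import path for externally produced DEU tables,
# and the significance/zeroing rules used downstream.

#' Read a bin-by-sample count table
#'
#' TSV with a `bin_id` column formatted `<cluster_id>:<bin_index>` followed
#' by one integer column per sample.
#'
#' @param path TSV path.
#' @return integer matrix, rownames = bin ids.
#' @export
read_count_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"bin_id" %in% names(df)) stop("count table lacks a 'bin_id' column: ", path)
  m <- as.matrix(df[, setdiff(names(df), "bin_id"), drop = FALSE])
  rownames(m) <- df$bin_id
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}

split_bin_ids <- function(ids) {
  pos <- regexpr(":[0-9]+$", ids)
  if (any(pos < 0)) stop("bin ids must look like '<cluster_id>:<bin_index>'")
  data.frame(cluster_id = substr(ids, 1L, pos - 1L),
             bin_index = as.integer(substring(ids, pos + 1L)),
             stringsAsFactors = FALSE)
}

#' Test differential exon usage between two conditions
#'
#' A deliberately simple usage statistic standing in for a full
#' negative-binomial GLM analysis: replicate counts are pooled by summation
#' per condition; for each exon bin the 2x2 table (bin count vs
#' rest-of-gene count, condition A vs condition B) is tested with a
#' two-sided Fisher exact test, and the effect size is the usage log2
#' fold change
#' \deqn{\mathrm{deu} = \log_2\frac{(b_B+0.5)/(r_B+0.5)}{(b_A+0.5)/(r_A+0.5)}}
#' (positive values mean relatively higher usage in condition B).
#' First-exon bins are dropped when `model` is supplied; genes with a single
#' remaining bin or zero total counts in either condition are reported with
#' `NA` values and excluded from testing.  `p_fdr` is Benjamini-Hochberg
#' adjusted within the comparison.
#'
#' @param counts integer matrix, rows named `<cluster_id>:<bin_index>`,
#'   columns = sample ids.
#' @param samples data frame mapping `sample` to `cell_type`.
#' @param cond_a,cond_b the two cell types to compare.
#' @param model optional filtered `ExonModel` used to drop first-exon bins
#'   and restrict to retained genes.
#' @return a `DeuTable` data frame: `comparison, cell_a, cell_b, cluster_id,
#'   bin_index, deu_value, p_raw, p_fdr, significant`.
#' @export
test_exon_usage <- function(counts, samples, cond_a, cond_b, model = NULL) {
  stopifnot(is.matrix(counts), all(c("sample", "cell_type") %in% names(samples)))
  for (cond in c(cond_a, cond_b)) {
    n_rep <- sum(samples$cell_type == cond)
    if (n_rep < 1L) stop("no samples for condition: ", cond)
  }
  sel_a <- samples$sample[samples$cell_type == cond_a]
  sel_b <- samples$sample[samples$cell_type == cond_b]
  if (!all(c(sel_a, sel_b) %in% colnames(counts))) {
    stop("count matrix lacks columns for some samples of ",
         cond_a, " / ", cond_b)
  }
  ids <- split_bin_ids(rownames(counts))
  keep <- rep(TRUE, nrow(counts))
  if (!is.null(model)) {
    b <- model$bins
    retained <- bin_key(mcols(b)$cluster_id[!mcols(b)$is_first_exon],
                        mcols(b)$bin_index[!mcols(b)$is_first_exon])
    keep <- rownames(counts) %in% retained
  }
  a <- rowSums(counts[, sel_a, drop = FALSE])
  b <- rowSums(counts[, sel_b, drop = FALSE])
  df <- data.frame(comparison = comparison_label(cond_a, cond_b),
                   cell_a = cond_a, cell_b = cond_b,
                   cluster_id = ids$cluster_id, bin_index = ids$bin_index,
                   bin_a = a, bin_b = b, stringsAsFactors = FALSE)[keep, ]
  gene_a <- tapply(df$bin_a, df$cluster_id, sum)
  gene_b <- tapply(df$bin_b, df$cluster_id, sum)
  n_bins <- table(df$cluster_id)
  df$rest_a <- as.integer(gene_a[df$cluster_id] - df$bin_a)
  df$rest_b <- as.integer(gene_b[df$cluster_id] - df$bin_b)
  testable <- gene_a[df$cluster_id] > 0 & gene_b[df$cluster_id] > 0 &
    n_bins[df$cluster_id] >= 2L
  df$deu_value <- ifelse(testable,
                         log2(((df$bin_b + 0.5) / (df$rest_b + 0.5)) /
                                ((df$bin_a + 0.5) / (df$rest_a + 0.5))),
                         NA_real_)
  df$p_raw <- NA_real_
  df$p_raw[testable] <- fisher_p2x2(df$bin_a[testable], df$rest_a[testable],
                                    df$bin_b[testable], df$rest_b[testable])
  df$p_fdr <- bh_adjust(df$p_raw)
  df$significant <- NA
  rownames(df) <- NULL
  df[, c("comparison", "cell_a", "cell_b", "cluster_id", "bin_index",
         "deu_value", "p_raw", "p_fdr", "significant")]
}

#' Import an externally produced DEU result table
#'
#' Normalizes a TSV from an external differential-exon-usage tool into a
#' `DeuTable`.  The `"generic"` dialect expects columns mappable to
#' `(gene, bin, log2fold, pvalue[, padj])`; the `"dexseq"` dialect expects
#' `groupID, featureID, pvalue, padj` and a column whose name starts with
#' `log2fold`.  A missing `padj` is recomputed by Benjamini-Hochberg.
#'
#' @param tsv_path path to the TSV.
#' @param dialect `"generic"` or `"dexseq"`.
#' @param comparison label to attach (default `"imported"`).
#' @return a `DeuTable` data frame as in [test_exon_usage()].
#' @export
import_deu_table <- function(tsv_path, dialect = c("generic", "dexseq"),
                             comparison = "imported") {
  dialect <- match.arg(dialect)
  df <- read.table(tsv_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(df)
  spec <- if (dialect == "dexseq") {
    list(gene = "groupID", bin = c("featureID", "exonID"),
         pvalue = c("pvalue", "p.value"), padj = "padj")
  } else {
    list(gene = c("gene", "gene_id", "cluster_id", "groupID"),
         bin = c("bin", "bin_index", "featureID"),
         log2fold = c("log2fold", "log2fc", "deu_value"),
         pvalue = c("pvalue", "p", "p_raw", "p.value"),
         padj = c("padj", "p_fdr", "p_adj"))
  }
  idx <- lapply(spec, match_column, found = cols)
  required <- setdiff(names(spec), "padj")
  if (dialect == "dexseq") {
    lf <- grep("^log2fold", cols)
    idx$log2fold <- if (length(lf)) lf[1L] else NA_integer_
    required <- c(required, "log2fold")
  }
  if (anyNA(unlist(idx[required]))) stop_schema("DEU import", spec, cols)
  bin_raw <- df[[idx$bin]]
  bin_index <- suppressWarnings(as.integer(gsub("[^0-9]", "", bin_raw)))
  if (anyNA(bin_index)) stop("could not derive integer bin indices from: ",
                             paste(head(unique(bin_raw)), collapse = ", "))
  out <- data.frame(comparison = comparison,
                    cell_a = NA_character_, cell_b = NA_character_,
                    cluster_id = as.character(df[[idx$gene]]),
                    bin_index = bin_index,
                    deu_value = as.numeric(df[[idx$log2fold]]),
                    p_raw = as.numeric(df[[idx$pvalue]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(bin_key(out$cluster_id, out$bin_index))) {
    stop("duplicate (gene, bin) rows in ", tsv_path)
  }
  out$p_fdr <- if (!is.na(idx$padj)) as.numeric(df[[idx$padj]]) else
    bh_adjust(out$p_raw)
  out$significant <- NA
  out
}

#' Apply DEU significance flags and the correlation-stage zeroing rule
#'
#' Sets `significant = (p_fdr <= alpha_fdr)` and forces `deu_value` to zero
#' wherever the raw (non-adjusted) p-value exceeds `zero_alpha`; the zeroing
#' rule deliberately uses the raw p-value so that the correlation stage
#' contrasts clearly differential exons against a flat background.
#'
#' @param deu_table a `DeuTable`.
#' @param alpha_fdr FDR threshold for the significance flag (default 0.05).
#' @param zero_alpha raw-p threshold for zeroing (default 0.05).
#' @return the table with `significant` set and `deu_value` zeroed.
#' @export
apply_deu_significance <- function(deu_table, alpha_fdr = 0.05,
                                   zero_alpha = 0.05) {
  stopifnot(all(c("deu_value", "p_raw", "p_fdr") %in% names(deu_table)))
  deu_table$significant <- !is.na(deu_table$p_fdr) &
    deu_table$p_fdr <= alpha_fdr
  zero <- is.na(deu_table$p_raw) | deu_table$p_raw > zero_alpha
  deu_table$deu_value[zero & !is.na(deu_table$deu_value)] <- 0
  deu_table
}

#' Write a DEU table as TSV
#' @param deu_table a `DeuTable`.
#' @param path output path.
#' @export
write_deu_table <- function(deu_table, path) {
  write.table(deu_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
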