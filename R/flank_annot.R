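# Flank annotation: intersect differential-peak records with exon flanks,
# keep the most significant peak per flank, pool the FDR correction across
# comparisons per mark, and reduce the two flank signals to one per exon.

dhm_to_granges <- function(dhm_table) {
  GRanges(dhm_table$contig, IRanges(dhm_table$start, dhm_table$end))
}

#' Annotate exon flanks with differential-peak signals
#'
#' A peak record is assigned to a flank iff their intervals overlap by at
#' least 1 bp.  When several records hit one flank (within one comparison
#' and mark), the record with the smallest raw p-value is kept (ties: larger
#' `|M|`, then leftmost start).  The FDR correction is then recomputed per
#' mark across \emph{all} retained (flank, comparison) records, and
#' `significant = (p_fdr <= alpha)`.
#'
#' @param flanks flank `GRanges` from [compute_flanks()].
#' @param dhm_table a `DhmTable` data frame carrying `comparison` and `mark`
#'   columns in addition to `contig, start, end, M, p_raw` (single-comparison
#'   tables may omit them; `"cmp"` / `"mark"` are filled in).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return `FlankSignalTable` data frame: `cluster_id, bin_index, side,
#'   comparison, mark, M, p_raw, p_fdr, significant`.
#' @export
annotate_flanks <- function(flanks, dhm_table, alpha = 0.05) {
  stopifnot(is(flanks, "GRanges"),
            all(c("contig", "start", "end", "M", "p_raw") %in% names(dhm_table)))
  if (!"comparison" %in% names(dhm_table)) dhm_table$comparison <- "cmp"
  if (!"mark" %in% names(dhm_table)) dhm_table$mark <- "mark"
  known <- as.character(unique(seqnames(flanks)))
  missing <- setdiff(unique(dhm_table$contig), known)
  if (length(missing) > 0L) {
    warning("peak contig(s) absent from annotation, records skipped: ",
            paste(missing, collapse = ", "))
    dhm_table <- dhm_table[!dhm_table$contig %in% missing, , drop = FALSE]
  }
  hit <- findOverlaps(flanks, dhm_to_granges(dhm_table), ignore.strand = TRUE)
  if (length(hit) == 0L) {
    return(data.frame(cluster_id = character(), bin_index = integer(),
                      side = character(), comparison = character(),
                      mark = character(), M = numeric(), p_raw = numeric(),
                      p_fdr = numeric(), significant = logical()))
  }
  fi <- queryHits(hit); pi <- subjectHits(hit)
  cand <- data.frame(cluster_id = mcols(flanks)$cluster_id[fi],
                     bin_index = mcols(flanks)$bin_index[fi],
                     side = mcols(flanks)$side[fi],
                     comparison = dhm_table$comparison[pi],
                     mark = dhm_table$mark[pi],
                     M = dhm_table$M[pi],
                     p_raw = dhm_table$p_raw[pi],
                     peak_start = dhm_table$start[pi],
                     stringsAsFactors = FALSE)
  # deterministic best-peak-per-flank rule: min p, then max |M|, then
  # leftmost peak start
  ord <- order(cand$cluster_id, cand$bin_index, cand$side, cand$comparison,
               cand$mark, cand$p_raw, -abs(cand$M), cand$peak_start)
  cand <- cand[ord, ]
  key <- paste(cand$cluster_id, cand$bin_index, cand$side, cand$comparison,
               cand$mark, sep = "\r")
  best <- cand[!duplicated(key), ]
  best$peak_start <- NULL
  best$p_fdr <- NA_real_
  for (m in unique(best$mark)) {
    sel <- best$mark == m
    best$p_fdr[sel] <- bh_adjust(best$p_raw[sel])
  }
  best$significant <- best$p_fdr <= alpha
  rownames(best) <- NULL
  best
}

#' Reduce the two flank signals of an exon to one signed M-value
#'
#' Per (exon bin, comparison, mark): among the exon's \emph{significant}
#' flank signals, `"min-p"` keeps the M of the flank with the smaller raw
#' p-value (ties: larger `|M|`), `"max-abs-M"` keeps the largest-magnitude M,
#' and `"mean"` averages them.  `M_exon = 0` when neither flank carries a
#' significant signal.  When `model` is supplied, the table is completed so
#' that every retained non-first-exon bin appears exactly once per
#' (comparison, mark) observed in `flank_signals`, with zeros.
#'
#' @param flank_signals `FlankSignalTable` from [annotate_flanks()].
#' @param model optional filtered `ExonModel` for grid completion.
#' @param policy `"min-p"` (default), `"max-abs-M"` or `"mean"`.
#' @return `ExonSignalTable` data frame: `cluster_id, bin_index, comparison,
#'   mark, M_exon`.
#' @export
reduce_to_exon_signal <- function(flank_signals, model = NULL,
                                  policy = c("min-p", "max-abs-M", "mean")) {
  policy <- match.arg(policy)
  fs <- flank_signals[flank_signals$significant %in% TRUE, , drop = FALSE]
  if (nrow(fs) > 0L) {
    ord <- switch(policy,
                  "min-p" = order(fs$p_raw, -abs(fs$M)),
                  "max-abs-M" = order(-abs(fs$M), fs$p_raw),
                  "mean" = seq_len(nrow(fs)))
    fs <- fs[ord, ]
    key <- paste(fs$cluster_id, fs$bin_index, fs$comparison, fs$mark,
                 sep = "\r")
    if (policy == "mean") {
      m <- tapply(fs$M, key, mean)
      first <- fs[!duplicated(key), ]
      first$M <- as.numeric(m[paste(first$cluster_id, first$bin_index,
                                    first$comparison, first$mark, sep = "\r")])
      fs <- first
    } else {
      fs <- fs[!duplicated(key), ]
    }
    sig <- data.frame(cluster_id = fs$cluster_id, bin_index = fs$bin_index,
                      comparison = fs$comparison, mark = fs$mark,
                      M_exon = fs$M, stringsAsFactors = FALSE)
  } else {
    sig <- data.frame(cluster_id = character(), bin_index = integer(),
                      comparison = character(), mark = character(),
                      M_exon = numeric())
  }
  if (is.null(model)) return(sig)
  b <- model$bins
  b <- b[!mcols(b)$is_first_exon]
  grid_cm <- unique(flank_signals[, c("comparison", "mark"), drop = FALSE])
  if (nrow(grid_cm) == 0L) grid_cm <- data.frame(comparison = character(),
                                                 mark = character())
  full <- merge(data.frame(cluster_id = mcols(b)$cluster_id,
                           bin_index = mcols(b)$bin_index),
                grid_cm, by = NULL)
  out <- merge(full, sig, all.x = TRUE,
               by = c("cluster_id", "bin_index", "comparison", "mark"))
  out$M_exon[is.na(out$M_exon)] <- 0
  out <- out[order(out$mark, out$comparison, out$cluster_id, out$bin_index), ]
  rownames(out) <- NULL
  out
}

#' Write a flank-signal table as TSV
#' @param flank_signals `FlankSignalTable`.
#' @param path output path.
#' @export
write_flank_signals <- function(flank_signals, path) {
  write.table(flank_signals, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
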