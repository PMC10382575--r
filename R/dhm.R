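# Differential histone modification: peak loading/merging, a simplified
# MA-plot normalization with z-testing standing in for a full differential
# peak model, and an import path for external differential-peak tables.

# Robust straight-line baseline via iteratively trimmed least squares:
# start from the median level, drop points whose residual exceeds 3 MADs,
# refit, iterate.  Genuinely differential peaks are excluded from the fit
# after the first pass, so they neither tilt the line (they sit at extreme
# A-values and would act as leverage points) nor inflate the intercept.
ma_baseline <- function(x, y, n_iter = 4L, k_trim = 3) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  a <- median(y); b <- 0
  for (it in seq_len(n_iter)) {
    r <- y - (a + b * x)
    s <- mad(r)
    keep <- if (s < 1e-12) rep(TRUE, length(r)) else abs(r) <= k_trim * s
    if (sum(keep) < 2L || length(unique(x[keep])) < 2L) break
    cf <- stats::coef(stats::lm.fit(cbind(1, x[keep]), y[keep]))
    if (anyNA(cf)) break
    a <- cf[1L]; b <- cf[2L]
  }
  c(intercept = a, slope = b)
}

#' Read a BED6+1 peak file
#'
#' Columns: chrom, start, end, name, score, strand, read density (column 7).
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of `GRanges` on ingest.
#'
#' @param path BED path.
#' @return `GRanges` with a `density` metadata column.
#' @export
read_peak_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 7L) stop("expected BED6+1 (density in column 7): ", path)
  dens <- as.numeric(df[[7L]])
  if (any(is.na(dens))) stop("non-numeric density values in ", path)
  if (any(dens < 0)) stop("negative peak density in ", path)
  GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]),
          strand = ifelse(df[[6L]] %in% c("+", "-"), df[[6L]], "*"),
          density = dens)
}

#' Load replicate peak files and merge them into one peak set
#'
#' Overlapping or abutting intervals across the replicate files are merged
#' into maximal intervals; read densities are summed over the merged
#' constituents.  Input need not be sorted.
#'
#' @param peaks one or more BED6+1 paths, or a list of `GRanges` with a
#'   `density` column (or a single such `GRanges`).
#' @return merged `GRanges` with summed `density`.
#' @export
load_and_merge_peaks <- function(peaks) {
  if (is(peaks, "GRanges")) peaks <- list(peaks)
  if (is.character(peaks)) peaks <- lapply(peaks, read_peak_bed)
  stopifnot(length(peaks) >= 1L)
  peaks <- lapply(peaks, function(p) {
    stopifnot(is(p, "GRanges"), "density" %in% names(mcols(p)))
    if (any(mcols(p)$density < 0)) stop("negative peak density")
    p
  })
  all <- unlist(GenomicRanges::GRangesList(lapply(peaks, function(p) {
    mcols(p) <- mcols(p)["density"]; p
  })))
  merged <- reduce(all, ignore.strand = TRUE)
  hit <- findOverlaps(all, merged, ignore.strand = TRUE)
  dens <- tapply(mcols(all)$density[queryHits(hit)], subjectHits(hit), sum)
  mcols(merged)$density <- as.numeric(dens[as.character(seq_along(merged))])
  merged
}

#' MA-normalize two peak sets and test for differential modification
#'
#' Both samples' merged peaks are projected onto a common reference (the
#' merged union of both sets).  Per reference peak, with summed densities
#' \eqn{x_A, x_B}:
#' \deqn{M = \log_2\frac{x_A + 0.5}{x_B + 0.5},\qquad
#'       A = \tfrac12 \log_2\left[(x_A + 0.5)(x_B + 0.5)\right].}
#' A straight-line baseline \eqn{M = a + bA} is fitted on the common peaks
#' (reference peaks overlapped by peaks of both samples) and removed, giving
#' the normalized \eqn{M'}.  Two-sided z-test p-values are computed against
#' a robust scale estimate (median absolute deviation) of the common-peak
#' \eqn{M'} — robust so that a minority of genuinely differential common
#' peaks does not inflate the null spread — then adjusted by
#' Benjamini-Hochberg; peaks are flagged differential when
#' `p_fdr <= fdr_alpha` and `|M'| >= m_min`.
#'
#' The baseline is estimated by iteratively trimmed least squares (fit,
#' drop points with residuals beyond 3 robust SDs, refit) rather than a
#' single ordinary fit: genuinely differential common peaks sit at extreme
#' A-values and would otherwise act as high-leverage points tilting the
#' line.
#'
#' @param peaks_a,peaks_b merged `GRanges` peak sets (see
#'   [load_and_merge_peaks()]) with `density` columns.
#' @param min_common minimum number of common peaks for baseline fitting.
#' @param fdr_alpha,m_min differential-call thresholds (defaults 0.05 and 1).
#' @return a `DhmTable` data frame: `contig, start, end, M, A, p_raw, p_fdr,
#'   is_dhm, common` (coordinates 1-based closed; `M` is the normalized
#'   value, positive when sample A is enriched).
#' @export
ma_normalize_and_test <- function(peaks_a, peaks_b, min_common = 10L,
                                  fdr_alpha = 0.05, m_min = 1) {
  stopifnot(is(peaks_a, "GRanges"), is(peaks_b, "GRanges"))
  ref <- reduce(c(GRanges(seqnames(peaks_a), IRanges(start(peaks_a), end(peaks_a))),
                  GRanges(seqnames(peaks_b), IRanges(start(peaks_b), end(peaks_b)))),
                ignore.strand = TRUE)
  sum_density <- function(p) {
    hit <- findOverlaps(p, ref, ignore.strand = TRUE)
    x <- rep(0, length(ref))
    s <- tapply(mcols(p)$density[queryHits(hit)], subjectHits(hit), sum)
    x[as.integer(names(s))] <- as.numeric(s)
    x
  }
  xa <- sum_density(peaks_a)
  xb <- sum_density(peaks_b)
  common <- countOverlaps(ref, peaks_a, ignore.strand = TRUE) > 0L &
    countOverlaps(ref, peaks_b, ignore.strand = TRUE) > 0L
  if (sum(common) < min_common) {
    stop("only ", sum(common), " common peaks; at least ", min_common,
         " are required for baseline fitting - provide larger peak sets")
  }
  M <- log2((xa + 0.5) / (xb + 0.5))
  A <- 0.5 * log2((xa + 0.5) * (xb + 0.5))
  fit <- ma_baseline(A[common], M[common])
  Mn <- M - (fit[1L] + fit[2L] * A)
  sd0 <- mad(Mn[common])
  p <- if (!is.finite(sd0) || sd0 < 1e-12) rep(1, length(Mn)) else
    2 * pnorm(-abs(Mn) / sd0)
  p_fdr <- bh_adjust(p)
  data.frame(contig = as.character(seqnames(ref)),
             start = start(ref), end = end(ref),
             M = Mn, A = A, p_raw = p, p_fdr = p_fdr,
             is_dhm = p_fdr <= fdr_alpha & abs(Mn) >= m_min,
             common = common, stringsAsFactors = FALSE)
}

#' Import an external differential-peak (MA) table
#'
#' Columns must be mappable to `(chrom, start, end, M_value, A_value, p)`;
#' `p_fdr` is recomputed by Benjamini-Hochberg and the differential flag
#' applies the `p_fdr <= fdr_alpha` and `|M| >= m_min` rule.  Coordinates in
#' the file are taken as 0-based half-open (BED-like) and converted.
#'
#' @param tsv_path path to the TSV.
#' @param fdr_alpha,m_min differential-call thresholds (defaults 0.05 and 1).
#' @return a `DhmTable` data frame as in [ma_normalize_and_test()].
#' @export
import_manorm_table <- function(tsv_path, fdr_alpha = 0.05, m_min = 1) {
  df <- read.table(tsv_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  spec <- list(chrom = c("chrom", "chr", "contig", "seqnames"),
               start = "start", end = "end",
               M = c("M_value", "M", "m_value"),
               A = c("A_value", "A", "a_value"),
               p = c("p", "pvalue", "p_value", "P_value"))
  idx <- lapply(spec, match_column, found = names(df))
  if (anyNA(unlist(idx))) stop_schema("MA-table import", spec, names(df))
  p_raw <- as.numeric(df[[idx$p]])
  p_fdr <- bh_adjust(p_raw)
  M <- as.numeric(df[[idx$M]])
  data.frame(contig = as.character(df[[idx$chrom]]),
             start = as.integer(df[[idx$start]]) + 1L,
             end = as.integer(df[[idx$end]]),
             M = M, A = as.numeric(df[[idx$A]]),
             p_raw = p_raw, p_fdr = p_fdr,
             is_dhm = p_fdr <= fdr_alpha & abs(M) >= m_min,
             common = NA, stringsAsFactors = FALSE)
}

#' Write a DHM table as TSV (coordinates 0-based half-open)
#' @param dhm_table a `DhmTable`.
#' @param path output path.
#' @export
write_dhm_table <- function(dhm_table, path) {
  out <- dhm_table
  out$start <- out$start - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
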