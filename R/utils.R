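# Internal helpers shared across modules.

#' Two-sided Fisher exact p-values for a batch of 2x2 tables
#'
#' Vectorized over rows of `(a, b, c, d)`, the table being
#' `rbind(c(a, b), c(c, d))`.  Uses the conditional hypergeometric
#' distribution with the usual "probabilities not exceeding that of the
#' observed table" two-sided rule, matching [stats::fisher.test()] for
#' 2x2 tables.
#'
#' @param a,b,c,d integer vectors of equal length; non-negative cell counts.
#' @return numeric vector of p-values.
#' @keywords internal
#' @noRd
fisher_p2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (anyNA(c(a[i], b[i], c[i], d[i]))) next
    m <- a[i] + b[i]          # row 1 margin
    nn <- c[i] + d[i]         # row 2 margin
    k <- a[i] + c[i]          # column 1 margin
    lo <- max(0L, k - nn)
    hi <- min(k, m)
    x <- lo:hi
    dens <- dhyper(x, m, nn, k)
    # relative tolerance as in fisher.test() to absorb float noise
    p[i] <- min(1, sum(dens[dens <= dens[a[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

# Benjamini-Hochberg with NA pass-through (NAs excluded from m).
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

# Key uniquely identifying an exon bin.
bin_key <- function(cluster_id, bin_index) paste0(cluster_id, ":", bin_index)

# Canonical comparison label for an unordered-but-directed cell type pair.
comparison_label <- function(cell_a, cell_b) paste0(cell_a, "_vs_", cell_b)

stop_schema <- function(what, expected, found) {
  stop(sprintf("%s: could not map required columns; expected one of {%s} for each of: %s (found columns: %s)",
               what, paste(unlist(expected), collapse = ", "),
               paste(names(expected), collapse = ", "),
               paste(found, collapse = ", ")), call. = FALSE)
}

# Pick the first matching column name (case-insensitive) from `candidates`,
# NA if none present.
match_column <- function(found, candidates) {
  hit <- match(tolower(candidates), tolower(found))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
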