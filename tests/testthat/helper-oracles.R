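# Independent brute-force oracles used to validate the fast implementations.

suppressPackageStartupMessages(library(GenomicRanges))

# Base-level flattening oracle: mark every base of a gene's exonic footprint
# with its covering-transcript set; maximal runs of a constant non-empty set
# are the expected bins (1-based closed coordinates, single contig).
oracle_flatten_gene <- function(ex) {
  lo <- min(ex$start)
  hi <- max(ex$end)
  covers <- vapply(lo:hi, function(p) {
    paste(sort(unique(ex$transcript_id[ex$start <= p & ex$end >= p])),
          collapse = ",")
  }, character(1))
  r <- rle(covers)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != ""
  data.frame(start = lo + starts[keep] - 1L, end = lo + ends[keep] - 1L)
}

# Random small gene model: <= 5 transcripts, <= 8 exons each, one gene.
random_gene_model <- function() {
  n_tx <- sample(1:5, 1)
  ex <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
    n_ex <- sample(1:8, 1)
    starts <- sort(sample(1:400, n_ex))
    widths <- sample(5:60, n_ex, replace = TRUE)
    ends <- starts + widths - 1L
    # enforce sorted exons separated by at least 1 intronic base
    # (abutting exons within one transcript are a single exon biologically)
    for (i in seq_len(n_ex)[-1]) {
      if (starts[i] <= ends[i - 1] + 1L) starts[i] <- ends[i - 1] + 2L
      ends[i] <- max(ends[i], starts[i] + 4L)
    }
    data.frame(contig = "chr1", start = starts, end = ends, strand = "+",
               gene_id = "G", transcript_id = paste0("T", t))
  }))
  ex
}

# Exhaustive conditional (Fisher) two-sided p for a 2x2 table via explicit
# enumeration of the hypergeometric pmf with choose().
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- a + b + c + d
  xs <- max(0, k - r2):min(k, r1)
  pmf <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(n, k))
  p_obs <- pmf[xs == a]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# All-pairs interval overlap oracle on two data frames with
# contig/start/end (1-based closed).
oracle_overlap_pairs <- function(q, s) {
  hits <- NULL
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$contig[i] == s$contig[j] &&
          q$start[i] <= s$end[j] && s$start[j] <= q$end[i]) {
        hits <- rbind(hits, c(i, j))
      }
    }
  }
  hits
}

# Adjusted Rand index by explicit pair enumeration.
oracle_ari <- function(x, y) {
  n <- length(x)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) a <- a + 1
      else if (sx && !sy) b <- b + 1
      else if (!sx && sy) cc <- cc + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)
  2 * (a * d - b * cc) / denom
}

# Small in-memory DEU/exon-signal fixture builders used across files.
make_deu_rows <- function(cluster_id, bins, deu, p_raw = NULL,
                          comparison = "A_vs_B", cell_a = "A", cell_b = "B") {
  if (is.null(p_raw)) p_raw <- ifelse(deu == 0, 0.5, 1e-4)
  data.frame(comparison = comparison, cell_a = cell_a, cell_b = cell_b,
             cluster_id = cluster_id, bin_index = bins, deu_value = deu,
             p_raw = p_raw, p_fdr = p_raw, significant = p_raw <= 0.05,
             stringsAsFactors = FALSE)
}

make_signal_rows <- function(cluster_id, bins, M,
                             comparison = "A_vs_B", mark = "H3K36me3") {
  data.frame(cluster_id = cluster_id, bin_index = bins,
             comparison = comparison, mark = mark, M_exon = M,
             stringsAsFactors = FALSE)
}
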