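# Seeded synthetic-data generator: a complete miniature study (annotation,
# replicate exon counts, peak sets, metadata, term map) with planted DEU,
# DHM, episplicing, cohort structure and one enriched term, plus the truth
# tables needed for recovery scoring.

#' Parameters for the synthetic-study generator
#'
#' Defaults describe the miniature study used throughout the test suite:
#' 6 cell types x 2 replicates x 300 genes, negative-binomial gene totals
#' allocated to exon bins by a Dirichlet-multinomial, planted usage shifts
#' of 2 log2 units on 40% of the exons of epispliced genes (10 exons each),
#' and flank peak densities whose log2 offsets follow
#' `coupling_slope * usage_shift + N(0, dhm_noise_sd)` for coupled genes.
#' Decoy genes exercise every gene-model exclusion filter.
#'
#' @param n_cell_types,n_replicates,n_genes cohort dimensions.
#' @param exons_per_gene integer range (min, max) for filler genes;
#'   epispliced genes always receive `epispliced_exons` exons.
#' @param epispliced_exons exon count of planted epispliced genes.
#' @param frac_overlapping,frac_duplicated,frac_multi_region,frac_single_exon
#'   fractions of `n_genes` turned into decoys for the corresponding filter.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion of the
#'   per-gene, per-sample read total.
#' @param dirichlet_conc concentration of the per-sample Dirichlet draw
#'   around the cell-type bin proportions (higher = tighter replicates).
#' @param deu_log2fc planted usage shift (log2 units).
#' @param deu_exon_frac fraction of a planted gene's exons receiving the
#'   shift (alternating signs).
#' @param n_epispliced,n_deu_only,n_dhm_only planted gene counts.
#' @param n_groups number of planted cell-type groups sharing epispliced
#'   gene pools.
#' @param coupling_slope slope tying flank log2 peak-density offsets to the
#'   planted usage shift (0 = null coupling).
#' @param dhm_noise_sd SD of the cell-level log2 density noise at flank
#'   peaks.
#' @param marks histone marks to simulate.
#' @param n_background_peaks intergenic peaks shared by all samples, used
#'   for MA-baseline fitting.
#' @param peak_density_mean median read density of a peak.
#' @param peak_strength_sd log2 SD of per-peak intrinsic strength (shared
#'   across cell types); spreads peaks along the A-axis as in real peak
#'   sets, which anchors the MA-baseline fit.
#' @param peak_nb_size Gamma-Poisson (negative-binomial) size of replicate
#'   peak read densities; smaller = noisier.
#' @param n_terms,planted_term_frac,term_bg_frac term-map shape: number of
#'   terms, fraction of epispliced genes carrying the planted term, and
#'   fraction of other genes carrying it.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the parameter set.
#' @return a validated `SimulationParams` list.
#' @export
simulation_params <- function(n_cell_types = 6L, n_replicates = 2L,
                              n_genes = 300L,
                              exons_per_gene = c(5L, 12L),
                              epispliced_exons = 10L,
                              frac_overlapping = 0.02,
                              frac_duplicated = 0.01,
                              frac_multi_region = 0.01,
                              frac_single_exon = 0.04,
                              nb_mean = 2000, nb_dispersion = 0.05,
                              dirichlet_conc = 100,
                              deu_log2fc = 2, deu_exon_frac = 0.4,
                              n_epispliced = 24L, n_deu_only = 20L,
                              n_dhm_only = 20L, n_groups = 2L,
                              coupling_slope = 1, dhm_noise_sd = 0.3,
                              marks = c("H3K36me3", "H3K27ac"),
                              n_background_peaks = 300L,
                              peak_density_mean = 50,
                              peak_strength_sd = 1.2,
                              peak_nb_size = 20,
                              n_terms = 20L, planted_term_frac = 0.8,
                              term_bg_frac = 0.05,
                              seed = 1L) {
  p <- as.list(environment())
  fracs <- c(p$frac_overlapping, p$frac_duplicated, p$frac_multi_region,
             p$frac_single_exon, p$deu_exon_frac, p$planted_term_frac,
             p$term_bg_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  if (p$n_cell_types < 2L || p$n_replicates < 1L || p$n_genes < 10L) {
    stop("infeasible cohort dimensions")
  }
  if (p$n_groups > p$n_cell_types) stop("more groups than cell types")
  if (p$dhm_noise_sd <= 0 || p$peak_nb_size <= 0) {
    stop("dhm_noise_sd and peak_nb_size must be > 0")
  }
  n_special <- p$n_epispliced + p$n_deu_only + p$n_dhm_only +
    ceiling(p$n_genes * (p$frac_overlapping + p$frac_duplicated +
                           p$frac_multi_region + p$frac_single_exon))
  if (n_special > p$n_genes) stop("planted and decoy genes exceed n_genes")
  structure(p, class = "SimulationParams")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- alpha
  x / sum(x)
}

#' Simulate a complete miniature episplicing study
#'
#' Generates annotation, replicate exon-bin counts, per-sample peak sets,
#' cell-type metadata, a gene-to-term map and the planted-truth tables, all
#' as a deterministic function of the seed.  When `dir` is given, every
#' artifact is also written in the file dialects the pipeline consumes
#' (GTF; bin-by-sample count TSV; BED6+1 peak files; metadata, term-map and
#' truth TSVs).
#'
#' @param params a `SimulationParams` list from [simulation_params()].
#' @param dir optional output directory.
#' @return a `SimulatedStudy` list: `exons` (annotation data frame),
#'   `counts`, `samples`, `peaks` (`[[cell_type]][[mark]]` lists of
#'   replicate `GRanges`), `metadata`, `term_map`, `truth`, `params`,
#'   `model` (the filtered `ExonModel` used to lay out the count rows).
#' @export
simulate_dataset <- function(params = simulation_params(), dir = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  p <- params
  set.seed(p$seed)

  cell_types <- sprintf("ct%02d", seq_len(p$n_cell_types))
  group_of <- setNames(sprintf("grp%d", rep_len(seq_len(p$n_groups),
                                                p$n_cell_types)), cell_types)

  ## ---- gene roster -------------------------------------------------------
  n_over <- 2L * ceiling(p$n_genes * p$frac_overlapping / 2)
  n_dup <- ceiling(p$n_genes * p$frac_duplicated)
  n_mr <- ceiling(p$n_genes * p$frac_multi_region)
  n_se <- ceiling(p$n_genes * p$frac_single_exon)
  gene_ids <- sprintf("G%04d", seq_len(p$n_genes))
  role <- rep("null", p$n_genes)
  cursor <- 1L
  take <- function(n) {
    i <- seq.int(cursor, length.out = n)
    cursor <<- cursor + n
    i
  }
  idx_epi <- take(p$n_epispliced); role[idx_epi] <- "epispliced"
  idx_deu <- take(p$n_deu_only); role[idx_deu] <- "deu_only"
  idx_dhm <- take(p$n_dhm_only); role[idx_dhm] <- "dhm_only"
  idx_over <- take(n_over); role[idx_over] <- "overlapping"
  idx_dup <- take(n_dup); role[idx_dup] <- "duplicated"
  idx_mr <- take(n_mr); role[idx_mr] <- "multi_region"
  idx_se <- take(n_se); role[idx_se] <- "single_exon"

  ## ---- annotation --------------------------------------------------------
  pos <- c(chr1 = 10000L, chr2 = 10000L)
  exon_rows <- list()
  gaps <- list()  # intergenic gaps usable for background peaks
  make_exons <- function(contig, start, n_ex) {
    widths <- sample(150:350, n_ex, replace = TRUE)
    introns <- if (n_ex > 1L) sample(600:1500, n_ex - 1L, replace = TRUE) else integer()
    starts <- start + cumsum(c(0L, widths[-n_ex] + introns))
    data.frame(contig = contig, start = starts, end = starts + widths - 1L)
  }
  for (gi in seq_len(p$n_genes)) {
    g <- gene_ids[gi]
    contig <- "chr1"
    strand <- sample(c("+", "-"), 1L)
    n_ex <- if (role[gi] == "epispliced") p$epispliced_exons
            else if (role[gi] == "single_exon") 1L
            else sample(p$exons_per_gene[1L]:p$exons_per_gene[2L], 1L)
    ex <- make_exons(contig, pos[[contig]], n_ex)
    tx <- list(T1 = ex)
    if (role[gi] == "null" && n_ex >= 4L && runif(1) < 0.2) {
      tx$T2 <- ex[-2L, , drop = FALSE]          # skipped internal exon
    } else if (role[gi] == "null" && n_ex >= 3L && runif(1) < 0.15) {
      ext <- ex                                  # extended terminal exon:
      if (strand == "+") ext$start[1L] <- ext$start[1L] - 50L  # forces a
      else ext$end[n_ex] <- ext$end[n_ex] + 50L  # boundary split on flatten
      tx$T2 <- ext
    } else if (role[gi] == "overlapping" &&
               gi %in% idx_over[seq_along(idx_over) %% 2L == 0L]) {
      # shift this decoy back onto the previous decoy's exons
      prev <- exon_rows[[length(exon_rows)]]
      ex <- make_exons(contig, min(prev$start) + 75L, n_ex)
      tx <- list(T1 = ex)
    } else if (role[gi] == "duplicated") {
      ex2 <- make_exons(contig, max(ex$end) + 50000L, n_ex)
      tx$T2 <- ex2                               # same id at a second locus
    } else if (role[gi] == "multi_region") {
      ex2 <- make_exons("chr2", pos[["chr2"]], max(2L, n_ex - 1L))
      pos[["chr2"]] <- max(ex2$end) + 10000L
      tx$T2 <- ex2
    }
    for (tn in names(tx)) {
      e <- tx[[tn]]
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(contig = e$contig, start = e$start, end = e$end,
                   strand = strand, gene_id = g,
                   transcript_id = paste0(g, ".", tn),
                   stringsAsFactors = FALSE)
    }
    span_end <- max(unlist(lapply(tx, function(e) e$end[e$contig == contig])))
    gaps[[length(gaps) + 1L]] <- c(span_end + 2000L, span_end + 8000L)
    pos[[contig]] <- max(pos[[contig]], span_end + 10000L)
  }
  exons <- do.call(rbind, exon_rows)

  ## ---- flattened layout for count rows ----------------------------------
  model_all <- flatten_gene_models(exons)
  filtered <- filter_gene_clusters(model_all)
  bins <- model_all$bins
  bin_ids <- bin_key(mcols(bins)$cluster_id, mcols(bins)$bin_index)
  n_bins_of <- table(mcols(bins)$cluster_id)

  ## ---- planted usage shifts ---------------------------------------------
  # s[bin, cell_type]: planted log2 usage offset
  s <- matrix(0, nrow = length(bins), ncol = p$n_cell_types,
              dimnames = list(bin_ids, cell_types))
  truth_deu <- list()
  truth_epi <- list()
  plant_gene <- function(g, cells, mark = NA_character_) {
    rows <- which(mcols(bins)$cluster_id == g)
    first <- mcols(bins)$is_first_exon[rows]
    eligible <- rows[!first]
    k <- max(1L, round(length(rows) * p$deu_exon_frac))
    k <- min(k, length(eligible))
    target <- sort(sample(eligible, k))
    signs <- rep_len(c(1, -1), k)
    s[target, cells] <<- signs * p$deu_log2fc
    data.frame(gene_id = g, bin_index = mcols(bins)$bin_index[target],
               shift = signs * p$deu_log2fc,
               cells = paste(cells, collapse = ","),
               mark = mark, stringsAsFactors = FALSE)
  }
  group_cells <- split(cell_types, group_of)
  epi_mark <- rep_len(p$marks, p$n_epispliced)
  epi_group <- rep_len(names(group_cells), p$n_epispliced)
  for (j in seq_along(idx_epi)) {
    g <- gene_ids[idx_epi[j]]
    td <- plant_gene(g, group_cells[[epi_group[j]]], epi_mark[j])
    truth_deu[[length(truth_deu) + 1L]] <- td
    truth_epi[[length(truth_epi) + 1L]] <-
      data.frame(gene_id = g, mark = epi_mark[j], group = epi_group[j],
                 n_deu_exons = nrow(td), stringsAsFactors = FALSE)
  }
  for (j in idx_deu) {
    truth_deu[[length(truth_deu) + 1L]] <-
      plant_gene(gene_ids[j], sample(cell_types, 1L))
  }

  ## ---- counts ------------------------------------------------------------
  samples <- expand.grid(rep = seq_len(p$n_replicates),
                         cell_type = cell_types, stringsAsFactors = FALSE)
  samples <- data.frame(sample = paste0(samples$cell_type, "_r", samples$rep),
                        cell_type = samples$cell_type,
                        replicate = samples$rep, stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow = length(bins), ncol = nrow(samples),
                   dimnames = list(bin_ids, samples$sample))
  gene_rows <- split(seq_along(bins), mcols(bins)$cluster_id)
  base_props <- lapply(gene_rows, function(r) rdirichlet1(rep(5, length(r))))
  size <- 1 / p$nb_dispersion
  for (si in seq_len(nrow(samples))) {
    ct <- samples$cell_type[si]
    for (g in names(gene_rows)) {
      r <- gene_rows[[g]]
      w <- base_props[[g]] * 2^s[r, ct]
      w <- w / sum(w)
      pr <- rdirichlet1(p$dirichlet_conc * w)
      tot <- rnbinom(1L, mu = p$nb_mean, size = size)
      counts[r, si] <- as.integer(rmultinom(1L, tot, pr))
    }
  }

  ## ---- peaks -------------------------------------------------------------
  gap_mat <- do.call(rbind, gaps)
  n_bg <- min(p$n_background_peaks, nrow(gap_mat))
  bg_idx <- sort(sample(nrow(gap_mat), n_bg))
  bg <- GRanges("chr1", IRanges(gap_mat[bg_idx, 1L],
                                gap_mat[bg_idx, 1L] + 399L))
  # flank peak scaffold: upstream-of-start window per planted/noise exon
  flank_peak <- function(rows) {
    GRanges(as.character(seqnames(bins))[rows],
            IRanges(pmax(1L, start(bins)[rows] - 180L),
                    pmax(21L, start(bins)[rows] - 21L)))
  }
  # l[bin, cell, mark]: planted log2 density offsets at flank peaks
  peak_rows <- list()   # per mark: integer bin rows carrying a peak
  offsets <- list()     # per mark: matrix bins x cells of log2 offsets
  for (m in p$marks) {
    peak_rows[[m]] <- integer()
    offsets[[m]] <- matrix(0, nrow = length(bins), ncol = p$n_cell_types,
                           dimnames = list(NULL, cell_types))
  }
  for (j in seq_along(idx_epi)) {
    g <- gene_ids[idx_epi[j]]
    m <- epi_mark[j]
    rows <- which(mcols(bins)$cluster_id == g & !mcols(bins)$is_first_exon)
    planted <- rows[s[rows, group_cells[[epi_group[j]]][1L]] != 0]
    extra <- setdiff(rows, planted)
    extra <- extra[seq_len(min(2L, length(extra)))]
    use <- c(planted, extra)
    peak_rows[[m]] <- c(peak_rows[[m]], use)
    offsets[[m]][use, ] <- p$coupling_slope * s[use, ] +
      matrix(rnorm(length(use) * p$n_cell_types, 0, p$dhm_noise_sd),
             ncol = p$n_cell_types)
  }
  for (j in idx_dhm) {
    g <- gene_ids[j]
    m <- sample(p$marks, 1L)
    rows <- which(mcols(bins)$cluster_id == g & !mcols(bins)$is_first_exon)
    use <- rows[seq_len(min(3L, length(rows)))]
    ct <- sample(cell_types, 1L)
    peak_rows[[m]] <- c(peak_rows[[m]], use)
    offsets[[m]][use, ct] <- sample(c(-1.8, 1.8), length(use), replace = TRUE)
  }
  # uncoupled noise-only flank peaks on a fifth of the null genes
  null_genes <- gene_ids[role == "null"]
  noisy <- sample(null_genes, max(0L, round(length(null_genes) / 5)))
  for (g in noisy) {
    m <- sample(p$marks, 1L)
    rows <- which(mcols(bins)$cluster_id == g & !mcols(bins)$is_first_exon)
    use <- rows[seq_len(min(2L, length(rows)))]
    peak_rows[[m]] <- c(peak_rows[[m]], use)
  }
  # intrinsic per-peak strengths, shared across cell types and replicates
  strength <- list()
  for (m in p$marks) {
    rows <- sort(unique(peak_rows[[m]]))
    strength[[m]] <- list(
      bg = p$peak_density_mean * 2^rnorm(length(bg), 0, p$peak_strength_sd),
      fp = p$peak_density_mean * 2^rnorm(length(rows), 0,
                                         p$peak_strength_sd))
  }
  peaks <- list()
  for (ct in cell_types) {
    peaks[[ct]] <- list()
    for (m in p$marks) {
      rows <- sort(unique(peak_rows[[m]]))
      fp <- flank_peak(rows)
      # Gamma-Poisson read densities around the cell-level mean
      mu <- c(strength[[m]]$bg,
              strength[[m]]$fp * 2^offsets[[m]][rows, ct])
      reps <- list()
      for (rp in seq_len(p$n_replicates)) {
        gr <- c(bg, fp)
        mcols(gr)$density <- rnbinom(length(mu), mu = mu,
                                     size = p$peak_nb_size)
        reps[[rp]] <- sort(gr, ignore.strand = TRUE)
      }
      peaks[[ct]][[m]] <- reps
    }
  }

  ## ---- metadata and term map --------------------------------------------
  metadata <- data.frame(
    cell_type = cell_types,
    group = unname(group_of),
    potency = ifelse(group_of == "grp1", "pluripotent", "differentiated"),
    sample_type = sample(c("tissue", "cell_line"), p$n_cell_types,
                         replace = TRUE),
    origin = sample(c("ectoderm", "mesoderm", "endoderm"), p$n_cell_types,
                    replace = TRUE),
    life_stage = sample(c("embryonic", "adult"), p$n_cell_types,
                        replace = TRUE),
    stringsAsFactors = FALSE)

  epi_genes <- gene_ids[idx_epi]
  planted_term <- "T01"
  tm <- list(data.frame(
    gene_id = c(sample(epi_genes, ceiling(p$planted_term_frac *
                                            length(epi_genes))),
                sample(setdiff(gene_ids, epi_genes),
                       ceiling(p$term_bg_frac *
                                 (p$n_genes - length(epi_genes))))),
    term_id = planted_term, stringsAsFactors = FALSE))
  for (t in seq(2L, p$n_terms)) {
    tm[[t]] <- data.frame(
      gene_id = sample(gene_ids, max(3L, round(0.1 * p$n_genes))),
      term_id = sprintf("T%02d", t), stringsAsFactors = FALSE)
  }
  term_map <- unique(do.call(rbind, tm))

  truth <- list(
    epispliced = do.call(rbind, truth_epi),
    deu_exons = do.call(rbind, truth_deu),
    groups = data.frame(cell_type = cell_types, group = unname(group_of),
                        stringsAsFactors = FALSE),
    term = planted_term,
    roles = data.frame(gene_id = gene_ids, role = role,
                       stringsAsFactors = FALSE))

  out <- structure(list(exons = exons, counts = counts, samples = samples,
                        peaks = peaks, metadata = metadata,
                        term_map = term_map, truth = truth, params = p,
                        model = filtered$model,
                        filter_report = filtered$report),
                   class = "SimulatedStudy")
  if (!is.null(dir)) write_simulated_study(out, dir)
  out
}

#' Write a simulated study to disk in the pipeline's file dialects
#'
#' @param study a `SimulatedStudy`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "SimulatedStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  ex <- study$exons
  gtf <- sprintf(
    "%s\tepisplicer\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ex$contig, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(gtf, file.path(dir, "annotation.gtf"))
  cm <- data.frame(bin_id = rownames(study$counts), study$counts,
                   check.names = FALSE)
  write.table(cm, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$term_map, file.path(dir, "term_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (ct in names(study$peaks)) {
    for (m in names(study$peaks[[ct]])) {
      for (rp in seq_along(study$peaks[[ct]][[m]])) {
        gr <- study$peaks[[ct]][[m]][[rp]]
        df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                         sprintf("%s_%s_peak%d", ct, m, seq_along(gr)), 0L,
                         ".", mcols(gr)$density)
        write.table(df, file.path(dir, "peaks",
                                  sprintf("%s_%s_rep%d.bed", ct, m, rp)),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
      }
    }
  }
  write.table(study$truth$epispliced, file.path(dir, "truth_epispliced.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$truth$deu_exons, file.path(dir, "truth_deu_exons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$truth$groups, file.path(dir, "truth_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate per-cell-type epispliced gene sets with planted group structure
#'
#' Directly generates an epispliced catalog (bypassing read-level
#' simulation): cell types fall into `n_groups` groups, each with its own
#' gene pool; a cell type carries each pool gene with probability
#' `keep_prob` plus `n_private` genes of its own.  Groups share no pool
#' genes, so between-group Jaccard similarity stays near zero while
#' within-group similarity is about `keep_prob^2 / (2 keep_prob - keep_prob^2)`.
#'
#' @param n_groups number of planted groups (default 2).
#' @param cells_per_group cell types per group (default 3).
#' @param pool_size genes per group pool (default 60).
#' @param keep_prob per-cell retention probability of a pool gene
#'   (default 0.8).
#' @param n_private private (noise) genes per cell type (default 3).
#' @param seed integer seed.
#' @return list: `sets` (named list of gene sets), `groups` (named group
#'   label per cell type).
#' @export
simulate_epispliced_catalog <- function(n_groups = 2L, cells_per_group = 3L,
                                        pool_size = 60L, keep_prob = 0.8,
                                        n_private = 3L, seed = 1L) {
  stopifnot(n_groups >= 2L, cells_per_group >= 2L, keep_prob > 0,
            keep_prob <= 1)
  set.seed(seed)
  sets <- list()
  groups <- character()
  priv <- 0L
  for (g in seq_len(n_groups)) {
    pool <- sprintf("g%d_gene%03d", g, seq_len(pool_size))
    for (cc in seq_len(cells_per_group)) {
      ct <- sprintf("grp%d_cell%d", g, cc)
      keep <- pool[runif(pool_size) < keep_prob]
      private <- sprintf("priv_gene%04d", priv + seq_len(n_private))
      priv <- priv + n_private
      sets[[ct]] <- sort(c(keep, private))
      groups[ct] <- sprintf("grp%d", g)
    }
  }
  list(sets = sets, groups = groups)
}

#' Score pipeline output against planted truth
#'
#' @param calls epispliced calls ([call_epispliced()] output) from a
#'   pipeline run on a simulated study.
#' @param truth the `truth` element of the corresponding `SimulatedStudy`.
#' @param cluster_scores optional `ClusterScores` whose clustering is also
#'   rescored against the planted groups.
#' @param similarity optional similarity matrix (one mark or combined) to
#'   cluster directly against the planted groups.
#' @param enrichment optional `EnrichmentTable` in which the planted term's
#'   rank (by fold enrichment) and adjusted p are reported.
#' @return list with `recall`, `precision`, `n_called`, `n_true`,
#'   `no_calls` flag, and (when inputs allow) `group_ari`, `term_rank`,
#'   `term_p_fdr`.
#' @export
score_recovery <- function(calls, truth, similarity = NULL,
                           enrichment = NULL) {
  true_pairs <- paste(truth$epispliced$gene_id, truth$epispliced$mark)
  called <- calls[calls$is_epispliced %in% TRUE, , drop = FALSE]
  bad <- setdiff(called$cluster_id, truth$roles$gene_id)
  if (length(bad) > 0L) {
    stop("called gene id(s) absent from the simulated study: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  called_pairs <- unique(paste(called$cluster_id, called$mark))
  tp <- length(intersect(called_pairs, true_pairs))
  out <- list(
    n_true = length(true_pairs), n_called = length(called_pairs),
    recall = if (length(true_pairs)) tp / length(true_pairs) else NA_real_,
    precision = if (length(called_pairs)) tp / length(called_pairs) else 0,
    no_calls = length(called_pairs) == 0L)
  if (!is.null(similarity)) {
    meta <- data.frame(cell_type = truth$groups$cell_type,
                       group = truth$groups$group)
    cs <- cluster_and_score(similarity, meta, schemes = "group")
    out$group_ari <- cs$ari[cs$scheme == "group"]
  }
  if (!is.null(enrichment)) {
    pos <- match(truth$term, enrichment$term_id)
    out$term_rank <- if (is.na(pos)) NA_integer_ else pos
    out$term_p_fdr <- if (is.na(pos)) NA_real_ else enrichment$p_fdr[pos]
  }
  out
}
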