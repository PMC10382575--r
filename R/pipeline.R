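# End-to-end orchestration: one configuration object driving
# flatten -> DEU -> DHM -> flank annotation -> association -> cohort ->
# enrichment, with per-stage TSV outputs and a machine-readable summary.

#' Build and validate a pipeline configuration
#'
#' Inputs may be file paths (GTF annotation, count TSV, BED peak directory,
#' metadata/term-map TSVs) or the corresponding in-memory objects; a whole
#' `SimulatedStudy` can be passed as `study`, which supplies every input at
#' once.
#'
#' @param study optional `SimulatedStudy` ([simulate_dataset()]).
#' @param annotation GTF path or exon data frame / `GRanges`.
#' @param counts count TSV path or bin-by-sample matrix.
#' @param samples sample-table TSV path or data frame (`sample, cell_type`).
#' @param peaks directory of `<cell>_<mark>_rep<i>.bed` files, or nested
#'   list `[[cell_type]][[mark]]` of replicate peak `GRanges`.
#' @param metadata metadata TSV path or data frame (cell_type + label
#'   schemes).
#' @param term_map gene-to-term TSV path or data frame.
#' @param out_dir optional output directory for stage TSVs and the summary.
#' @param flank_width exon-flank width in bp (default 200).
#' @param deu_alpha_fdr,zero_alpha DEU significance and zeroing thresholds.
#' @param strict_alpha,max_ubiquity,ubiquity_mode non-ubiquity filter
#'   settings (defaults 1e-4, 25, `"fixed"`).
#' @param use_pooled_filter run the pooled one-vs-rest filter (default TRUE).
#' @param dhm_fdr,m_min differential-modification call thresholds.
#' @param reduce_policy two-flank reduction policy (default `"min-p"`).
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param pooling_unit odds-ratio event unit (`"pooled"` or
#'   `"per-comparison"`).
#' @param r_min,cor_alpha epispliced-call thresholds (defaults 0.5, 0.05).
#' @param enrich_alpha enrichment FDR threshold (default 0.05).
#' @param linkage hierarchical clustering linkage (default `"average"`).
#' @param seed integer seed (stages are deterministic; the seed fixes any
#'   simulation embedded in the config).
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(study = NULL, annotation = NULL, counts = NULL,
                            samples = NULL, peaks = NULL, metadata = NULL,
                            term_map = NULL, out_dir = NULL,
                            flank_width = 200L, deu_alpha_fdr = 0.05,
                            zero_alpha = 0.05, strict_alpha = 1e-4,
                            max_ubiquity = 25L, ubiquity_mode = "fixed",
                            use_pooled_filter = TRUE, dhm_fdr = 0.05,
                            m_min = 1, reduce_policy = "min-p",
                            cor_method = "pearson", pooling_unit = "pooled",
                            r_min = 0.5, cor_alpha = 0.05,
                            enrich_alpha = 0.05, linkage = "average",
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(study)) {
    stopifnot(inherits(study, "SimulatedStudy"))
    cfg$annotation <- study$exons
    cfg$counts <- study$counts
    cfg$samples <- study$samples
    cfg$peaks <- study$peaks
    cfg$metadata <- study$metadata
    cfg$term_map <- study$term_map
  }
  for (alpha in c("deu_alpha_fdr", "zero_alpha", "strict_alpha", "dhm_fdr",
                  "cor_alpha", "enrich_alpha")) {
    v <- cfg[[alpha]]
    if (!is.numeric(v) || v <= 0 || v > 1) stop(alpha, " must be in (0, 1]")
  }
  if (!is.numeric(cfg$r_min) || cfg$r_min < 0 || cfg$r_min > 1) {
    stop("r_min must be in [0, 1]")
  }
  if (cfg$flank_width <= 0) stop("flank_width must be positive")
  for (path_arg in c("annotation", "counts", "samples", "peaks", "metadata",
                     "term_map")) {
    v <- cfg[[path_arg]]
    if (is.character(v) && length(v) == 1L && !file.exists(v)) {
      stop("configured ", path_arg, " path does not exist: ", v)
    }
  }
  if (is.null(cfg$annotation) || is.null(cfg$counts) || is.null(cfg$samples)) {
    stop("annotation, counts and samples are required")
  }
  structure(cfg, class = "PipelineConfig")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML maps argument names of [pipeline_config()] to values; relative
#' paths are resolved against the YAML's directory.
#'
#' @param path YAML path.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("annotation", "counts", "samples", "peaks", "metadata",
              "term_map", "out_dir")) {
    if (!is.null(raw[[k]]) && is.character(raw[[k]]) &&
        !startsWith(raw[[k]], "/")) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

read_peak_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (length(files) == 0L) stop("no BED files in peak directory: ", dir)
  meta <- regmatches(basename(files),
                     regexec("^(.+)_([^_]+)_rep([0-9]+)\\.bed$",
                             basename(files)))
  bad <- vapply(meta, length, integer(1)) != 4L
  if (any(bad)) stop("peak file name(s) not matching <cell>_<mark>_rep<i>.bed: ",
                     paste(basename(files)[bad], collapse = ", "))
  peaks <- list()
  for (i in seq_along(files)) {
    ct <- meta[[i]][2L]; m <- meta[[i]][3L]
    peaks[[ct]][[m]] <- c(peaks[[ct]][[m]], list(read_peak_bed(files[i])))
  }
  peaks
}

stage_msg <- function(...) message("[episplicer] ", ...)

#' Run the full episplicing pipeline
#'
#' Executes flatten, pairwise DEU, the non-ubiquity and pooled filters,
#' pairwise DHM per mark, flank annotation, odds-ratio association, per-gene
#' correlation with epispliced calling, Jaccard/clustering of cell types,
#' and term enrichment.  Stage tables are written under `out_dir` (when
#' set) together with `summary.json`.
#'
#' The sign convention is aligned across stages: for the comparison
#' (A, B), `deu_value` is the usage log2 fold change of B relative to A and
#' the normalized M-value is the peak-density log2 ratio of B over A.
#'
#' @param config a `PipelineConfig`.
#' @return a `PipelineResult` list with every stage's table, the epispliced
#'   catalog, similarity matrices, cluster scores, enrichment table and the
#'   `summary` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  set.seed(cfg$seed)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  # short fingerprint of the configuration, stamped into stage outputs
  cfg_hash <- local({
    tmp <- tempfile()
    on.exit(unlink(tmp))
    scalarish <- vapply(cfg, function(x) is.atomic(x) && length(x) <= 100,
                        logical(1))
    dput(cfg[scalarish], file = tmp)
    substr(unname(tools::md5sum(tmp)), 1L, 12L)
  })
  provenance <- paste0("# episplicer stage output; config ", cfg_hash,
                       "; seed ", cfg$seed)
  emit <- function(obj, name, writer = write.table) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    if (identical(writer, write.table)) {
      writeLines(provenance, path)
      suppressWarnings(write.table(obj, path, sep = "\t", quote = FALSE,
                                   row.names = FALSE, append = TRUE))
    } else {
      writer(obj, path)
    }
  }

  ## stage 1: annotation
  stage_msg("flattening annotation")
  exons <- cfg$annotation
  model_all <- if (is.character(exons)) parse_and_flatten(exons) else
    flatten_gene_models(exons)
  filt <- filter_gene_clusters(model_all)
  model <- filt$model
  flanks <- compute_flanks(model, width = cfg$flank_width)
  emit(model, "exon_model.tsv", write_exon_model)
  emit(flanks, "flanks.bed", write_flanks_bed)

  ## stage 2: pairwise DEU
  counts <- if (is.character(cfg$counts)) read_count_table(cfg$counts) else
    cfg$counts
  samples <- if (is.character(cfg$samples)) {
    read.table(cfg$samples, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  } else cfg$samples
  comparisons <- enumerate_comparisons(unique(samples$cell_type))
  stage_msg("pairwise DEU over ", nrow(comparisons), " comparisons")
  deu_list <- lapply(seq_len(nrow(comparisons)), function(i) {
    apply_deu_significance(
      test_exon_usage(counts, samples, comparisons$cell_a[i],
                      comparisons$cell_b[i], model = model),
      alpha_fdr = cfg$deu_alpha_fdr, zero_alpha = cfg$zero_alpha)
  })
  deu_all <- do.call(rbind, deu_list)

  ## stage 3: cohort filters
  ubiq <- ubiquity_filter(deu_all, strict_alpha = cfg$strict_alpha,
                          max_count = cfg$max_ubiquity,
                          mode = cfg$ubiquity_mode)
  stage_msg(length(ubiq$genes), " genes carry non-ubiquitous DEU exons")
  deu_background <- unique(
    deu_all$cluster_id[deu_all$significant %in% TRUE])
  deu <- deu_all[deu_all$cluster_id %in% ubiq$genes, , drop = FALSE]
  keep_bins <- mcols(model$bins)$cluster_id %in% ubiq$genes
  model_sub <- structure(list(bins = model$bins[keep_bins],
                              genes = model$genes[
                                model$genes$gene_id %in% ubiq$genes, ,
                                drop = FALSE]),
                         class = "ExonModel")
  if (cfg$use_pooled_filter &&
      length(unique(samples$cell_type)) >= 3L && length(ubiq$genes) > 0L) {
    stage_msg("pooled one-vs-rest filter")
    pooled <- pooled_filter(counts, samples, alpha = cfg$deu_alpha_fdr,
                            model = model_sub)
    deu <- apply_pooled_filter(deu, pooled$keys)
  } else {
    pooled <- NULL
  }
  emit(deu, "deu.tsv")

  ## stage 4: pairwise DHM per mark
  dhm_all <- NULL
  if (!is.null(cfg$peaks)) {
    peaks <- if (is.character(cfg$peaks)) read_peak_dir(cfg$peaks) else
      cfg$peaks
    merged <- lapply(peaks, function(by_mark)
      lapply(by_mark, load_and_merge_peaks))
    marks <- unique(unlist(lapply(merged, names)))
    stage_msg("pairwise DHM for mark(s): ", paste(marks, collapse = ", "))
    dhm_rows <- list()
    for (m in marks) {
      for (i in seq_len(nrow(comparisons))) {
        a <- comparisons$cell_a[i]; b <- comparisons$cell_b[i]
        if (is.null(merged[[a]][[m]]) || is.null(merged[[b]][[m]])) next
        # peaks_a = B so that positive M matches positive deu_value (B up)
        t <- ma_normalize_and_test(merged[[b]][[m]], merged[[a]][[m]],
                                   fdr_alpha = cfg$dhm_fdr,
                                   m_min = cfg$m_min)
        t$comparison <- comparisons$comparison[i]
        t$mark <- m
        dhm_rows[[length(dhm_rows) + 1L]] <- t
      }
    }
    dhm_all <- do.call(rbind, dhm_rows)
  }

  ## stage 5: flank annotation and exon signals
  if (!is.null(dhm_all)) {
    stage_msg("annotating flanks")
    flanks_sub <- flanks[mcols(flanks)$cluster_id %in% ubiq$genes]
    flank_signals <- annotate_flanks(flanks_sub, dhm_all,
                                     alpha = cfg$dhm_fdr)
    exon_signals <- reduce_to_exon_signal(flank_signals, model = model_sub,
                                          policy = cfg$reduce_policy)
    emit(flank_signals, "flank_signals.tsv")
    dhm_background <- unique(
      flank_signals$cluster_id[flank_signals$significant %in% TRUE])
  } else {
    flank_signals <- exon_signals <- NULL
    dhm_background <- character()
  }

  ## stage 6: association
  assoc_global <- assoc_gene <- correlations <- calls <- catalog <- NULL
  if (!is.null(exon_signals) && nrow(exon_signals) > 0L) {
    stage_msg("odds-ratio association and per-gene correlation")
    flags <- exon_event_flags(deu, flank_signals, unit = cfg$pooling_unit)
    assoc_global <- do.call(rbind, lapply(split(flags, flags$mark),
      function(f) {
        r <- or_from_flags(f$deu, f$dhm)
        cbind(data.frame(mark = f$mark[1L]), r)
      }))
    rownames(assoc_global) <- NULL
    assoc_gene <- lapply(split(flags, flags$mark), grouped_association)
    correlations <- gene_deu_dhm_correlation(deu, exon_signals,
                                             method = cfg$cor_method)
    calls <- call_epispliced(correlations, r_min = cfg$r_min,
                             alpha = cfg$cor_alpha)
    catalog <- epispliced_catalog(calls,
                                  cell_types = unique(samples$cell_type))
    emit(assoc_global, "association_global.tsv")
    emit(calls, "epispliced_calls.tsv")
  }

  ## stage 7: cohort similarity and clustering
  similarity <- cluster_scores <- NULL
  if (!is.null(catalog)) {
    similarity <- jaccard_similarity(catalog)
    emit(similarity, "similarity.tsv", write_similarity)
    metadata <- cfg$metadata
    if (is.character(metadata)) {
      metadata <- read.table(metadata, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    }
    if (!is.null(metadata)) {
      schemes <- setdiff(names(metadata), "cell_type")
      cluster_scores <- lapply(similarity, function(J) {
        if (nrow(J) < 3L) return(NULL)
        cluster_and_score(J, metadata, schemes = schemes,
                          linkage = cfg$linkage)
      })
    }
  }

  ## stage 8: enrichment
  enrichment <- NULL
  term_map <- cfg$term_map
  if (is.character(term_map)) {
    term_map <- read.table(term_map, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  background <- sort(unique(c(deu_background, dhm_background)))
  if (!is.null(term_map) && !is.null(catalog)) {
    genes <- sort(unique(unlist(
      catalog[[if ("combined" %in% names(catalog)) "combined" else 1L]])))
    genes <- intersect(genes, background)
    if (length(genes) > 0L) {
      stage_msg("term enrichment on ", length(genes), " epispliced genes")
      enrichment <- term_enrichment(genes, background, term_map,
                                    alpha = cfg$enrich_alpha)
      emit(enrichment, "enrichment.tsv")
    } else {
      stage_msg("no epispliced genes in background; enrichment skipped")
    }
  }

  ## summary
  epi_counts <- if (!is.null(catalog)) {
    lapply(catalog, function(sets) vapply(sets, length, integer(1)))
  } else NULL
  ari_table <- if (!is.null(cluster_scores)) {
    lapply(cluster_scores[!vapply(cluster_scores, is.null, logical(1))],
           function(cs) setNames(cs$ari, cs$scheme))
  } else NULL
  summary <- list(
    n_genes_input = filt$report$input,
    n_genes_retained = filt$report$retained,
    filter_removed = as.list(filt$report$removed),
    n_comparisons = nrow(comparisons),
    n_nonubiquitous_genes = length(ubiq$genes),
    global_or = if (!is.null(assoc_global))
      setNames(as.list(assoc_global$or), assoc_global$mark) else NULL,
    epispliced_counts = epi_counts,
    ari = ari_table,
    n_background_genes = length(background))
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(model = model, filter_report = filt$report,
                 flanks = flanks, comparisons = comparisons,
                 deu = deu, deu_all = deu_all, ubiquity = ubiq,
                 pooled = pooled, dhm = dhm_all,
                 flank_signals = flank_signals, exon_signals = exon_signals,
                 association_global = assoc_global,
                 association_gene = assoc_gene,
                 correlations = correlations, calls = calls,
                 catalog = catalog, similarity = similarity,
                 cluster_scores = cluster_scores, enrichment = enrichment,
                 background = background, summary = summary,
                 config = cfg),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("episplicer pipeline result\n")
  cat("  genes retained:", x$summary$n_genes_retained, "of",
      x$summary$n_genes_input, "\n")
  cat("  comparisons:", x$summary$n_comparisons, "\n")
  if (!is.null(x$calls)) {
    cat("  epispliced calls:", sum(x$calls$is_epispliced), "\n")
  }
  invisible(x)
}
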