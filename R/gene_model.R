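# Gene-model module: GTF ingestion, exon flattening into disjoint counting
# bins, gene-cluster exclusion filters, and 200-bp exon flank derivation.

#' Read exon-level gene annotation from a GTF file
#'
#' Reads a GTF (Ensembl/GENCODE attribute dialect) and returns the exon
#' records as a [GenomicRanges::GRanges] with `gene_id` and `transcript_id`
#' metadata columns.  Coordinates follow the usual GTF convention (1-based,
#' closed) as represented by `GRanges`; all text output written by this
#' package (BED, flat TSV) uses 0-based half-open coordinates.
#'
#' @param gtf_path path to a readable GTF file.
#' @return `GRanges` of exons with `gene_id`, `transcript_id` columns.
#' @export
read_gene_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("annotation file not found: ", gtf_path)
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", gtf_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!all(c("gene_id", "transcript_id") %in% names(mcols(gr)))) {
    stop("GTF lacks gene_id/transcript_id attributes: ", gtf_path)
  }
  ex <- gr[!is.na(mcols(gr)$type) & mcols(gr)$type == "exon"]
  # transcripts declared but owning no exon records are malformed
  if ("transcript" %in% as.character(mcols(gr)$type)) {
    tx_declared <- unique(mcols(gr)$transcript_id[mcols(gr)$type == "transcript"])
    tx_with_exons <- unique(mcols(ex)$transcript_id)
    orphan <- setdiff(tx_declared[!is.na(tx_declared)], tx_with_exons)
    if (length(orphan) > 0L) {
      stop("transcript(s) with zero exons in '", gtf_path, "': ",
           paste(head(orphan, 5L), collapse = ", "))
    }
  }
  if (length(ex) == 0L) stop("no exon records in GTF: ", gtf_path)
  mcols(ex) <- mcols(ex)[, c("gene_id", "transcript_id")]
  ex
}

as_exon_granges <- function(exons) {
  if (is(exons, "GRanges")) {
    stopifnot(all(c("gene_id", "transcript_id") %in% names(mcols(exons))))
    return(exons)
  }
  stopifnot(is.data.frame(exons),
            all(c("contig", "start", "end", "gene_id", "transcript_id") %in%
                  names(exons)))
  strand <- if ("strand" %in% names(exons)) exons$strand else "*"
  GRanges(exons$contig, IRanges(exons$start, exons$end), strand = strand,
          gene_id = exons$gene_id, transcript_id = exons$transcript_id)
}

#' Flatten transcript exons into disjoint, numbered counting bins
#'
#' For every gene, the union of its transcripts' exons is split at every
#' distinct exon boundary, yielding pairwise-disjoint bins whose union equals
#' the exonic footprint of the gene exactly.  Bins are numbered `1..k`
#' ascending by genomic coordinate (contig, then start) irrespective of
#' strand.  A bin is flagged `is_first_exon` when it overlaps the 5'-most
#' exon (strand-aware) of any transcript of the gene; such bins are excluded
#' from flank derivation and downstream usage testing because signal there is
#' dominated by alternative-promoter effects rather than splicing.
#'
#' @param exons exon annotation: a `GRanges` with `gene_id` and
#'   `transcript_id` metadata columns, or a data frame with columns
#'   `contig, start, end, strand, gene_id, transcript_id` (1-based closed).
#' @return An object of class `ExonModel`: list with
#'   \describe{
#'     \item{bins}{`GRanges` with `cluster_id`, `bin_index`, `is_first_exon`.}
#'     \item{genes}{per-gene bookkeeping used by [filter_gene_clusters()].}
#'   }
#' @examples
#' ex <- data.frame(contig = "chr1", start = c(101, 301, 101, 301),
#'                  end = c(200, 400, 250, 400), strand = "+",
#'                  gene_id = "G", transcript_id = rep(c("T1", "T2"), each = 2))
#' flatten_gene_models(ex)$bins
#' @export
flatten_gene_models <- function(exons) {
  ex <- as_exon_granges(exons)
  if (any(is.na(mcols(ex)$gene_id)) || any(mcols(ex)$gene_id == "")) {
    stop("exon records with empty gene_id")
  }
  gene_ids <- unique(mcols(ex)$gene_id)
  bins_list <- vector("list", length(gene_ids))
  genes <- data.frame(gene_id = gene_ids, n_bins = NA_integer_,
                      n_contigs = NA_integer_, n_strands = NA_integer_,
                      max_loci_per_contig = NA_integer_,
                      stringsAsFactors = FALSE)
  for (gi in seq_along(gene_ids)) {
    g <- ex[mcols(ex)$gene_id == gene_ids[gi]]
    # disjoin splits the exon union at every distinct boundary
    b <- disjoin(g, ignore.strand = TRUE)
    b <- sort(b, ignore.strand = TRUE)
    strand(b) <- if (length(unique(as.character(strand(g)))) == 1L)
      as.character(strand(g))[1L] else "*"
    # 5'-most exon per transcript, by strand
    first_ex <- lapply(split(g, mcols(g)$transcript_id), function(tx) {
      s <- as.character(strand(tx))[1L]
      if (s == "-") tx[which.max(end(tx))] else tx[which.min(start(tx))]
    })
    first_ex <- unlist(GenomicRanges::GRangesList(unname(first_ex)))
    is_first <- countOverlaps(b, first_ex, ignore.strand = TRUE) > 0L
    mcols(b) <- DataFrame(cluster_id = gene_ids[gi],
                          bin_index = seq_along(b),
                          is_first_exon = is_first)
    bins_list[[gi]] <- b
    # transcript-locus bookkeeping for the duplicate/multi-region filters
    gdf <- data.frame(contig = as.character(seqnames(g)), start = start(g),
                      end = end(g), tx = mcols(g)$transcript_id,
                      stringsAsFactors = FALSE)
    spans <- do.call(rbind, lapply(split(gdf, paste(gdf$tx, gdf$contig)),
      function(d) data.frame(contig = d$contig[1L], start = min(d$start),
                             end = max(d$end))))
    genes$n_contigs[gi] <- length(unique(as.character(seqnames(g))))
    genes$n_strands[gi] <- length(unique(as.character(strand(g))))
    genes$max_loci_per_contig[gi] <- max(vapply(
      split(spans, spans$contig),
      function(d) length(reduce(IRanges(d$start, d$end))), integer(1)))
    genes$n_bins[gi] <- length(b)
  }
  bins <- unlist(GenomicRanges::GRangesList(bins_list))
  names(bins) <- NULL
  structure(list(bins = bins, genes = genes), class = "ExonModel")
}

#' Parse a GTF and flatten it in one step
#'
#' @inheritParams read_gene_annotation
#' @return an `ExonModel`; see [flatten_gene_models()].
#' @export
parse_and_flatten <- function(gtf_path) {
  flatten_gene_models(read_gene_annotation(gtf_path))
}

#' @export
print.ExonModel <- function(x, ...) {
  cat("ExonModel:", nrow(x$genes), "gene cluster(s),",
      length(x$bins), "exon bin(s)\n")
  invisible(x)
}

#' Apply gene-cluster exclusion filters
#'
#' Removes, in this fixed reporting order (the retained set is the same
#' whichever order the rules are applied in):
#' \enumerate{
#'   \item genes sharing at least 1 bp of exonic sequence with a different
#'     gene (all members of the overlapping cluster are removed);
#'   \item duplicated gene ids: the same id annotated at two or more
#'     separate loci on one contig;
#'   \item multi-region genes: bins spanning more than one contig or strand;
#'   \item single-exon genes (exactly one bin after flattening).
#' }
#'
#' @param model an `ExonModel` from [flatten_gene_models()].
#' @return list with `model` (filtered `ExonModel`) and `report`
#'   (`FilterReport`: input/retained totals and per-rule removal counts).
#' @export
filter_gene_clusters <- function(model) {
  stopifnot(inherits(model, "ExonModel"))
  bins <- model$bins
  genes <- model$genes
  gid <- genes$gene_id

  ov <- findOverlaps(bins, bins, ignore.strand = TRUE)
  ov <- ov[mcols(bins)$cluster_id[queryHits(ov)] !=
             mcols(bins)$cluster_id[subjectHits(ov)]]
  rule1 <- unique(mcols(bins)$cluster_id[queryHits(ov)])
  rule2 <- gid[genes$max_loci_per_contig >= 2L]
  rule3 <- gid[genes$n_contigs > 1L | genes$n_strands > 1L]
  rule4 <- gid[genes$n_bins == 1L]

  assigned <- setNames(rep(NA_character_, length(gid)), gid)
  assigned[intersect(names(assigned), rule4)] <- "single_exon"
  assigned[intersect(names(assigned), rule3)] <- "multi_region"
  assigned[intersect(names(assigned), rule2)] <- "duplicated"
  assigned[intersect(names(assigned), rule1)] <- "overlapping"
  removed <- names(assigned)[!is.na(assigned)]

  keep <- !(mcols(bins)$cluster_id %in% removed)
  out <- structure(list(bins = bins[keep],
                        genes = genes[!(gid %in% removed), , drop = FALSE]),
                   class = "ExonModel")
  report <- structure(list(
    input = length(gid),
    retained = length(gid) - length(removed),
    removed = c(overlapping = sum(assigned == "overlapping", na.rm = TRUE),
                duplicated = sum(assigned == "duplicated", na.rm = TRUE),
                multi_region = sum(assigned == "multi_region", na.rm = TRUE),
                single_exon = sum(assigned == "single_exon", na.rm = TRUE))),
    class = "FilterReport")
  list(model = out, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", x$input, "genes in,", x$retained, "retained\n")
  print(x$removed)
  invisible(x)
}

#' Derive intronic exon flanks
#'
#' Each retained, non-first-exon bin owns two flanks on the intronic side of
#' its junctions: `width` bp upstream of the bin start and `width` bp
#' downstream of the bin end.  Flanks are clipped at the contig origin;
#' flanks clipped away entirely are dropped.  First-exon bins receive no
#' flanks.
#'
#' @param model filtered `ExonModel`.
#' @param width flank width in bp (default 200).
#' @param include_first also emit flanks for first-exon bins (default FALSE).
#' @return `GRanges` of flanks with `cluster_id`, `bin_index`,
#'   `side` (`"upstream"`/`"downstream"`) metadata columns.
#' @export
compute_flanks <- function(model, width = 200L, include_first = FALSE) {
  stopifnot(inherits(model, "ExonModel"))
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("flank width must be a single positive number")
  }
  width <- as.integer(width)
  bins <- model$bins
  if (!include_first) bins <- bins[!mcols(bins)$is_first_exon]
  up <- GRanges(seqnames(bins),
                IRanges(pmax(1L, start(bins) - width),
                        width = pmin(width, start(bins) - 1L)),
                strand = strand(bins))
  keep_up <- start(bins) > 1L
  mcols(up) <- DataFrame(cluster_id = mcols(bins)$cluster_id,
                         bin_index = mcols(bins)$bin_index,
                         side = "upstream")
  dn <- GRanges(seqnames(bins), IRanges(end(bins) + 1L, end(bins) + width),
                strand = strand(bins))
  mcols(dn) <- DataFrame(cluster_id = mcols(bins)$cluster_id,
                         bin_index = mcols(bins)$bin_index,
                         side = "downstream")
  fl <- c(up[keep_up], dn)
  sort(fl, ignore.strand = TRUE)
}

#' Write a flattened exon model as a flat TSV
#'
#' Columns: cluster_id, bin_index, contig, start, end, strand,
#' is_first_exon; coordinates 0-based half-open.
#'
#' @param model an `ExonModel`.
#' @param path output path.
#' @export
write_exon_model <- function(model, path) {
  b <- model$bins
  df <- data.frame(cluster_id = mcols(b)$cluster_id,
                   bin_index = mcols(b)$bin_index,
                   contig = as.character(seqnames(b)),
                   start = start(b) - 1L, end = end(b),
                   strand = as.character(strand(b)),
                   is_first_exon = mcols(b)$is_first_exon)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write flanks as BED6
#'
#' @param flanks flank `GRanges` from [compute_flanks()].
#' @param path output path.
#' @export
write_flanks_bed <- function(flanks, path) {
  df <- data.frame(chrom = as.character(seqnames(flanks)),
                   start = start(flanks) - 1L, end = end(flanks),
                   name = paste(mcols(flanks)$cluster_id,
                                mcols(flanks)$bin_index,
                                mcols(flanks)$side, sep = ":"),
                   score = 0L,
                   strand = sub("\\*", ".", as.character(strand(flanks))))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
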