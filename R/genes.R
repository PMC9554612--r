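# Candidate genes: extract gene models inside candidate windows, filter by
# expression in relevant tissues, and test co-localization with known
# genes.

#' Read gene models
#'
#' Accepts either a GFF3 file (gene features are extracted) or a TSV with
#' columns `gene_id`, `chr`, `start_bp`, `end_bp` (optional `description`).
#'
#' @param path input path; `.gff`/`.gff3` extensions are parsed as GFF3.
#' @return data.frame with `gene_id`, `chr`, `start_bp`, `end_bp`,
#'   `description`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(gr$type) == "gene"]
    ids <- gr$ID %||% gr$gene_id %||% gr$Name
    df <- data.frame(
      gene_id = as.character(ids),
      chr = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr),
      description = if (!is.null(gr$description))
        as.character(gr$description) else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_strict(path, required = c("gene_id", "chr", "start_bp",
                                             "end_bp"))
    if (is.null(df$description)) df$description <- NA_character_
  }
  as_gene_models(df)
}

#' @rdname read_gene_models
#' @param df data.frame with the gene-model columns.
#' @export
as_gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chr", "start_bp", "end_bp") %in% names(df)))
  if (any(df$start_bp > df$end_bp)) {
    stop_metaqtl("metaqtl_input_error", "gene start_bp > end_bp")
  }
  if (anyDuplicated(df$gene_id)) {
    stop_metaqtl("metaqtl_input_error", "duplicate gene_id")
  }
  df
}

#' Genes inside candidate-gene windows of promising meta-QTLs
#'
#' Only regions backed by at least `min_member_qtls` initial QTLs
#' ("promising" MQTLs) are scanned. A gene belongs to a window iff the two
#' intervals overlap by at least 1 bp (inclusive bounds).
#'
#' @param genes gene models ([as_gene_models()]).
#' @param windows data.frame from [gene_windows()] (needs `mqtl_id`, `chr`,
#'   `win_start_bp`, `win_end_bp`).
#' @param regions region table supplying member counts (`mqtl_id`,
#'   `n_qtls`).
#' @param min_member_qtls minimum member-QTL count (default 3).
#' @return data.frame of (mqtl_id, gene_id, chr, start_bp, end_bp,
#'   description) pairs.
#' @export
genes_in_windows <- function(genes, windows, regions, min_member_qtls = 3) {
  keep <- regions$mqtl_id[regions$n_qtls >= min_member_qtls]
  windows <- windows[windows$mqtl_id %in% keep, , drop = FALSE]
  empty <- data.frame(mqtl_id = character(0), gene_id = character(0),
                      chr = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), description = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(windows) || !nrow(genes)) return(empty)
  gp <- granges_pair(windows$chr, windows$win_start_bp,
                     windows$win_end_bp,
                     genes$chr, genes$start_bp, genes$end_bp)
  ov <- GenomicRanges::findOverlaps(gp$a, gp$b)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    mqtl_id = windows$mqtl_id[qi], gene_id = genes$gene_id[si],
    chr = genes$chr[si], start_bp = genes$start_bp[si],
    end_bp = genes$end_bp[si],
    description = genes$description[si] %||% NA_character_,
    stringsAsFactors = FALSE)
  out[order(out$mqtl_id, out$start_bp, out$gene_id), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Filter window genes by expression in relevant tissues
#'
#' A gene is kept iff its TPM strictly exceeds `tpm_threshold` in at least
#' one sample belonging to a relevant tissue. Genes absent from the
#' expression matrix are treated as not expressed (with a warning).
#'
#' @param gene_hits output of [genes_in_windows()].
#' @param expr expression matrix: data.frame/matrix with rownames (or a
#'   `gene_id` column) and one column per sample, TPM units.
#' @param tissues named character vector or data.frame mapping sample
#'   (column) names to tissue tags.
#' @param relevant tissue tags considered relevant (default grain, spike
#'   and senescing flag leaf).
#' @param tpm_threshold strict TPM cutoff (default 2).
#' @return subset of `gene_hits` for significantly expressed genes.
#' @export
filter_expressed <- function(gene_hits, expr, tissues,
                             relevant = c("grain", "spike",
                                          "flag_leaf_senescence"),
                             tpm_threshold = 2) {
  if (!length(relevant)) {
    stop_metaqtl("metaqtl_config_error", "relevant tissue set is empty")
  }
  if (is.data.frame(tissues)) {
    tissues <- stats::setNames(tissues$tissue, tissues$sample)
  }
  if (!is.null(expr$gene_id)) {
    rownames(expr) <- expr$gene_id
    expr$gene_id <- NULL
  }
  expr <- as.matrix(expr)
  rel_samples <- names(tissues)[tissues %in% relevant]
  rel_samples <- intersect(rel_samples, colnames(expr))
  ids <- unique(gene_hits$gene_id)
  absent <- setdiff(ids, rownames(expr))
  if (length(absent)) {
    warning(sprintf("%d gene(s) absent from expression matrix; treated as not expressed",
                    length(absent)))
  }
  present <- intersect(ids, rownames(expr))
  expressed <- if (length(rel_samples) && length(present)) {
    present[apply(expr[present, rel_samples, drop = FALSE] > tpm_threshold,
                  1, any)]
  } else character(0)
  out <- gene_hits[gene_hits$gene_id %in% expressed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-localization of known trait genes with meta-QTL regions
#'
#' A known gene co-localizes with a region iff it overlaps the region's
#' full anchored physical interval (inclusive, >= 1 bp).
#'
#' @param known gene models of previously characterised trait genes.
#' @param intervals anchored intervals ([anchor_regions()]).
#' @return data.frame of (mqtl_id, gene_id) co-localization pairs.
#' @export
known_gene_colocalization <- function(known, intervals) {
  intervals <- intervals[intervals$anchored, , drop = FALSE]
  empty <- data.frame(mqtl_id = character(0), gene_id = character(0),
                      chr = character(0), stringsAsFactors = FALSE)
  if (!nrow(known) || !nrow(intervals)) return(empty)
  gp <- granges_pair(intervals$chr, intervals$start_bp, intervals$end_bp,
                     known$chr, known$start_bp, known$end_bp)
  ov <- GenomicRanges::findOverlaps(gp$a, gp$b)
  out <- data.frame(
    mqtl_id = intervals$mqtl_id[S4Vectors::queryHits(ov)],
    gene_id = known$gene_id[S4Vectors::subjectHits(ov)],
    chr = known$chr[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
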