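# GWAS cross-verification: a region is "GWAS verified" when at least one
# significant SNP / marker-trait association (MTA) falls inside its full
# physical interval (inclusive bounds at both ends).

#' Read a GWAS MTA table
#' @param path TSV with columns `snp_id`, `chr`, `bp` (optional `study_id`,
#'   `trait`).
#' @return data.frame.
#' @export
read_mta_table <- function(path) {
  df <- read_tsv_strict(path, required = c("snp_id", "chr", "bp"))
  df$bp <- as.numeric(df$bp)
  if (any(df$bp < 0, na.rm = TRUE)) {
    stop_metaqtl("metaqtl_input_error", "MTA bp positions must be >= 0")
  }
  df
}

#' Verify regions against GWAS marker-trait associations
#'
#' An MTA co-localizes with a region iff it lies on the same chromosome
#' with `start_bp <= bp <= end_bp` (the full anchored interval, not the
#' candidate-gene window). Duplicate MTAs (same `snp_id` and `bp`) are
#' collapsed first. Unanchored regions are skipped with a warning.
#'
#' @param intervals anchored intervals ([anchor_regions()] output).
#' @param mtas MTA data.frame (`snp_id`, `chr`, `bp`).
#' @return list with `pairs` (region x SNP data.frame), `hits` (per-region
#'   SNP id list), `n_verified`, `n_mtas_colocalized`.
#' @export
verify_regions <- function(intervals, mtas) {
  drop <- !intervals$anchored
  if (any(drop)) {
    warning(sprintf("%d unanchored region(s) skipped", sum(drop)))
    intervals <- intervals[!drop, , drop = FALSE]
  }
  mtas <- mtas[!duplicated(paste(mtas$snp_id, mtas$bp)), , drop = FALSE]
  pairs <- data.frame(mqtl_id = character(0), snp_id = character(0),
                      chr = character(0), bp = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(intervals) && nrow(mtas)) {
    gp <- granges_pair(intervals$chr, intervals$start_bp, intervals$end_bp,
                       mtas$chr, mtas$bp, mtas$bp)
    ov <- GenomicRanges::findOverlaps(gp$a, gp$b)
    pairs <- data.frame(
      mqtl_id = intervals$mqtl_id[S4Vectors::queryHits(ov)],
      snp_id = mtas$snp_id[S4Vectors::subjectHits(ov)],
      chr = mtas$chr[S4Vectors::subjectHits(ov)],
      bp = mtas$bp[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
  }
  hits <- split(pairs$snp_id, factor(pairs$mqtl_id,
                                     levels = intervals$mqtl_id))
  list(pairs = pairs, hits = hits,
       n_verified = sum(vapply(hits, length, integer(1)) > 0),
       n_mtas_colocalized = length(unique(paste(pairs$snp_id, pairs$bp))))
}
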