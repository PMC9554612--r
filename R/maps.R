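# Linkage maps: ordered marker -> cM assignments per chromosome.
#
# A linkage_map is a data.frame (map_id, chr, marker, position_cM) with
# positions strictly increasing within each chromosome and unique marker
# names per chromosome. A consensus_map has the same shape plus a
# n_source_maps column and per-marker provenance.

#' Construct a linkage map
#'
#' @param map_id identifier of the map (usually the study id).
#' @param df data.frame with columns `chr`, `marker`, `position_cM` (and
#'   optionally `map_id`, overridden by the argument).
#' @return a `linkage_map` data.frame sorted by chromosome then position.
#' @export
linkage_map <- function(map_id, df) {
  stopifnot(all(c("chr", "marker", "position_cM") %in% names(df)))
  df <- data.frame(map_id = map_id, chr = as.character(df$chr),
                   marker = as.character(df$marker),
                   position_cM = as.numeric(df$position_cM),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chr, df$position_cM, df$marker), ]
  rownames(df) <- NULL
  for (ch in unique(df$chr)) {
    seg <- df[df$chr == ch, ]
    if (anyDuplicated(seg$marker)) {
      stop_metaqtl("metaqtl_map_error",
                   "duplicate marker on chromosome %s of map %s", ch, map_id)
    }
    if (nrow(seg) > 1 && any(diff(seg$position_cM) <= 0)) {
      stop_metaqtl("metaqtl_map_error",
                   "positions not strictly increasing on chromosome %s of map %s",
                   ch, map_id)
    }
  }
  structure(df, class = c("linkage_map", "data.frame"))
}

#' Read linkage maps from a TSV file
#'
#' Expects columns `map_id`, `chr`, `marker`, `position_cM`; returns one
#' [linkage_map()] per distinct `map_id`.
#'
#' @param path TSV path.
#' @return named list of `linkage_map` objects.
#' @export
read_linkage_maps <- function(path) {
  df <- read_tsv_strict(path, required = c("map_id", "chr", "marker",
                                           "position_cM"))
  ids <- unique(df$map_id)
  stats::setNames(
    lapply(ids, function(id) linkage_map(id, df[df$map_id == id, ])),
    ids
  )
}

#' Write a (consensus or linkage) map to TSV
#' @param m a `linkage_map` or `consensus_map`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_map <- function(m, path) {
  write_tsv(as.data.frame(m), path)
}

map_chromosome <- function(m, chr) {
  seg <- m[m$chr == chr, , drop = FALSE]
  seg[order(seg$position_cM, seg$marker), , drop = FALSE]
}

#' Per-chromosome summary statistics of a map
#'
#' Length (last minus first position), marker count and density
#' (markers/cM) per chromosome, with sub-genome and total aggregates.
#' Density is `NA` for degenerate (single-marker or zero-length)
#' chromosomes.
#'
#' @param m a `linkage_map` or `consensus_map`.
#' @return list with `per_chromosome` data.frame, `per_subgenome`
#'   data.frame and `total` row.
#' @export
map_stats <- function(m) {
  chrs <- sort(unique(m$chr))
  per <- do.call(rbind, lapply(chrs, function(ch) {
    seg <- map_chromosome(m, ch)
    len <- if (nrow(seg) > 1) max(seg$position_cM) - min(seg$position_cM) else 0
    data.frame(chr = ch, n_markers = nrow(seg), length_cM = len,
               density = if (len > 0) nrow(seg) / len else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per$subgenome <- subgenome(per$chr)
  agg <- function(rows) {
    data.frame(n_markers = sum(rows$n_markers),
               length_cM = sum(rows$length_cM),
               density = if (sum(rows$length_cM) > 0)
                 sum(rows$n_markers) / sum(rows$length_cM) else NA_real_)
  }
  sgs <- sort(unique(per$subgenome[!is.na(per$subgenome)]))
  per_sg <- do.call(rbind, lapply(sgs, function(s) {
    cbind(subgenome = s, agg(per[!is.na(per$subgenome) &
                                   per$subgenome == s, ]))
  }))
  list(per_chromosome = per, per_subgenome = per_sg, total = agg(per))
}
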