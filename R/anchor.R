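# Physical anchoring: convert meta-QTL genetic intervals to base-pair
# intervals via a marker physical-position lookup table, interpolate the
# peak, and derive the candidate-gene window.
#
# bp coordinates are 1-based inclusive throughout; BED output alone uses
# the 0-based half-open convention.

#' Read a marker physical-position table
#'
#' @param path TSV with columns `marker`, `chr`, `bp`.
#' @return validated data.frame (one position per marker/chromosome).
#' @export
read_marker_table <- function(path) {
  df <- read_tsv_strict(path, required = c("marker", "chr", "bp"))
  as_marker_table(df)
}

#' @rdname read_marker_table
#' @param df data.frame with `marker`, `chr`, `bp` columns.
#' @export
as_marker_table <- function(df) {
  stopifnot(all(c("marker", "chr", "bp") %in% names(df)))
  df$bp <- as.numeric(df$bp)
  if (any(df$bp < 0, na.rm = TRUE)) {
    stop_metaqtl("metaqtl_input_error", "bp positions must be >= 0")
  }
  if (anyDuplicated(paste(tolower(df$marker), df$chr))) {
    stop_metaqtl("metaqtl_input_error",
                 "duplicate (marker, chromosome) entries in physical table")
  }
  df
}

lookup_bp <- function(table, marker, chr) {
  hit <- table[tolower(table$marker) == tolower(marker) &
                 table$chr == chr, ]
  if (nrow(hit) == 1) hit$bp else NA_real_
}

# Nearest anchorable marker: inside the CI first, then outside within
# `max_outside_cM` of the CI bounds. Returns list(marker, cM, bp) or NULL.
fallback_anchor <- function(region, cmap, table, side, max_outside_cM = 5) {
  seg <- map_chromosome(cmap, region$chr)
  if (!nrow(seg)) return(NULL)
  seg$bp <- vapply(seg$marker, lookup_bp, numeric(1), table = table,
                   chr = region$chr)
  seg <- seg[!is.na(seg$bp), ]
  if (!nrow(seg)) return(NULL)
  inside <- seg[seg$position_cM >= region$ci_lo &
                  seg$position_cM <= region$ci_hi, ]
  pick <- function(cand, target) {
    if (!nrow(cand)) return(NULL)
    i <- which.min(abs(cand$position_cM - target))
    list(marker = cand$marker[i], cM = cand$position_cM[i], bp = cand$bp[i])
  }
  target <- if (side == "lo") region$ci_lo else region$ci_hi
  res <- pick(inside, target)
  if (!is.null(res)) return(res)
  near <- seg[seg$position_cM >= region$ci_lo - max_outside_cM &
                seg$position_cM <= region$ci_hi + max_outside_cM, ]
  pick(near, target)
}

#' Anchor a meta-QTL region to physical coordinates
#'
#' Uses the region's two flanking markers (falling back to the nearest
#' anchorable markers inside the CI, then outside within 5 cM). The
#' interval is the sorted bp pair; the peak bp comes from linear cM-to-bp
#' interpolation between the anchors.
#'
#' @param region single region row (from `meta_qtl()$regions` or a region
#'   table) with `mqtl_id`, `chr`, `position`, `ci_lo`, `ci_hi`,
#'   `flank_lo`, `flank_hi`.
#' @param cmap consensus map (for anchor cM positions and fallbacks).
#' @param table marker physical table ([as_marker_table()]).
#' @return one-row data.frame: `mqtl_id`, `chr`, `start_bp`, `end_bp`,
#'   `span_bp`, `peak_bp`, `anchored` (logical), `degenerate` (logical),
#'   `provenance` (text notes on fallbacks).
#' @export
anchor_mqtl <- function(region, cmap, table) {
  notes <- character(0)
  get_anchor <- function(mk, side) {
    if (!is.na(mk)) {
      bp <- lookup_bp(table, mk, region$chr)
      seg <- map_chromosome(cmap, region$chr)
      cM <- seg$position_cM[match(tolower(mk), tolower(seg$marker))]
      if (!is.na(bp) && length(cM) == 1 && !is.na(cM)) {
        return(list(marker = mk, cM = cM, bp = bp))
      }
    }
    fb <- fallback_anchor(region, cmap, table, side)
    if (!is.null(fb)) {
      notes <<- c(notes, sprintf("%s anchor substituted by %s", side,
                                 fb$marker))
    }
    fb
  }
  a_lo <- get_anchor(region$flank_lo, "lo")
  a_hi <- get_anchor(region$flank_hi, "hi")
  unanchored <- data.frame(
    mqtl_id = region$mqtl_id, chr = region$chr, start_bp = NA_real_,
    end_bp = NA_real_, span_bp = NA_real_, peak_bp = NA_real_,
    anchored = FALSE, degenerate = FALSE,
    provenance = "unanchored: no flanking marker with physical position",
    stringsAsFactors = FALSE)
  if (is.null(a_lo) || is.null(a_hi)) return(unanchored)
  bp <- sort(c(a_lo$bp, a_hi$bp))
  degenerate <- bp[1] == bp[2]
  peak_bp <- if (degenerate || a_lo$cM == a_hi$cM) {
    if (!degenerate) notes <- c(notes, "zero cM span; peak at interval start")
    bp[1]
  } else {
    a_lo$bp + (region$position - a_lo$cM) / (a_hi$cM - a_lo$cM) *
      (a_hi$bp - a_lo$bp)
  }
  peak_bp <- min(max(peak_bp, bp[1]), bp[2])
  data.frame(
    mqtl_id = region$mqtl_id, chr = region$chr, start_bp = bp[1],
    end_bp = bp[2], span_bp = bp[2] - bp[1], peak_bp = peak_bp,
    anchored = TRUE, degenerate = degenerate,
    provenance = paste(notes, collapse = "; "),
    stringsAsFactors = FALSE)
}

#' Anchor every region of a region table
#'
#' @param regions region data.frame.
#' @param cmap consensus map.
#' @param table marker physical table.
#' @return data.frame of [anchor_mqtl()] rows, one per region.
#' @export
anchor_regions <- function(regions, cmap, table) {
  rows <- lapply(seq_len(nrow(regions)), function(i)
    anchor_mqtl(regions[i, ], cmap, table))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate-gene window of an anchored interval
#'
#' Intervals narrower than `window_mb` megabases are scanned whole;
#' wider intervals are reduced to `window_mb` Mb centred on the
#' interpolated peak, clipped so the window never leaves the interval.
#'
#' @param interval one anchored row from [anchor_mqtl()].
#' @param window_mb window size in Mb (default 2).
#' @return the interval row with `win_start_bp` and `win_end_bp` added.
#' @export
gene_window <- function(interval, window_mb = 2) {
  if (!isTRUE(interval$anchored)) {
    stop_metaqtl("metaqtl_input_error",
                 "cannot derive a gene window for an unanchored interval")
  }
  w <- window_mb * 1e6
  if (interval$span_bp < w) {
    interval$win_start_bp <- interval$start_bp
    interval$win_end_bp <- interval$end_bp
  } else {
    # window centred on the peak, clipped (not shifted) to the interval
    interval$win_start_bp <- max(interval$peak_bp - w / 2, interval$start_bp)
    interval$win_end_bp <- min(interval$peak_bp + w / 2, interval$end_bp)
  }
  interval
}

#' Gene windows for a table of anchored intervals
#' @param intervals data.frame from [anchor_regions()]; unanchored rows are
#'   dropped with a warning.
#' @param window_mb window size in Mb.
#' @return data.frame with window columns added.
#' @export
gene_windows <- function(intervals, window_mb = 2) {
  drop <- !intervals$anchored
  if (any(drop)) {
    warning(sprintf("%d unanchored region(s) skipped", sum(drop)))
    intervals <- intervals[!drop, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i)
    gene_window(intervals[i, ], window_mb)))
  rownames(out) <- NULL
  out
}

#' Write anchored windows as BED
#'
#' BED uses 0-based half-open coordinates; the package's own tables stay
#' 1-based inclusive.
#'
#' @param intervals data.frame with `chr`, `win_start_bp`, `win_end_bp`,
#'   `mqtl_id`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_windows_bed <- function(intervals, path) {
  bed <- data.frame(intervals$chr,
                    format(intervals$win_start_bp - 1, scientific = FALSE,
                           trim = TRUE),
                    format(intervals$win_end_bp, scientific = FALSE,
                           trim = TRUE),
                    intervals$mqtl_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
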