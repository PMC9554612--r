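# QTL projection: transfer peaks and CIs from a study map onto the
# consensus map by local flanking-marker scaling.
#
# For each QTL the closest pair of markers shared by its source map and the
# consensus map and bracketing the peak is used as the anchor pair; all
# source coordinates x map affinely to
#   c(M_L) + (x - s(M_L)) * ratio,   ratio = (c(M_R)-c(M_L))/(s(M_R)-s(M_L)).
# The projected 95% CI width divided by 3.92 (= 2 x 1.96) gives the
# standard deviation attached to the projected position.

REJECTION_CODES <- c("NO_COMMON_MARKERS", "INVERTED_ANCHORS",
                     "EXTREME_RATIO", "CHR_ABSENT", "ZERO_SPAN")

#' Project one QTL onto the consensus map
#'
#' @param q single-row (completed) `qtl_catalog` record.
#' @param source the study's [linkage_map()].
#' @param cmap the consensus map.
#' @param ratio_bounds admissible range for the local scale ratio; anchor
#'   pairs implying a ratio outside it are rejected with `EXTREME_RATIO`.
#' @return a list: either `list(ok = TRUE, row = <data.frame>)` with the
#'   projected record, or `list(ok = FALSE, reason = <code>)`.
#' @export
project_qtl <- function(q, source, cmap, ratio_bounds = c(0.1, 10)) {
  reject <- function(code) list(ok = FALSE, reason = code)
  if (is.na(q$peak_cM) || is.na(q$ci_lo_cM) || is.na(q$ci_hi_cM)) {
    stop_metaqtl("metaqtl_input_error",
                 "record %s is not completed (missing peak or CI)", q$qtl_id)
  }
  cseg <- map_chromosome(cmap, q$chr)
  if (nrow(cseg) == 0) return(reject("CHR_ABSENT"))
  sseg <- map_chromosome(source, q$chr)
  common <- intersect(tolower(sseg$marker), tolower(cseg$marker))
  if (length(common) < 2) return(reject("NO_COMMON_MARKERS"))
  s_pos <- sseg$position_cM[match(common, tolower(sseg$marker))]
  c_pos <- cseg$position_cM[match(common, tolower(cseg$marker))]
  ord <- order(s_pos)
  common <- common[ord]; s_pos <- s_pos[ord]; c_pos <- c_pos[ord]
  peak <- q$peak_cM
  iL <- which(s_pos <= peak)
  iR <- which(s_pos >= peak)
  extrapolated <- FALSE
  if (length(iL) && length(iR)) {
    iL <- max(iL); iR <- min(iR)
    if (iL == iR) {                       # peak sits exactly on a marker
      if (iR < length(common)) iR <- iR + 1 else iL <- iL - 1
    }
  } else if (!length(iL)) {               # peak left of all common markers
    iL <- 1; iR <- 2; extrapolated <- TRUE
  } else {                                # peak right of all common markers
    iL <- length(common) - 1; iR <- length(common); extrapolated <- TRUE
  }
  span_s <- s_pos[iR] - s_pos[iL]
  if (span_s <= 0) return(reject("ZERO_SPAN"))
  span_c <- c_pos[iR] - c_pos[iL]
  if (span_c <= 0) return(reject("INVERTED_ANCHORS"))
  ratio <- span_c / span_s
  if (ratio < ratio_bounds[1] || ratio > ratio_bounds[2]) {
    return(reject("EXTREME_RATIO"))
  }
  tr <- function(x) c_pos[iL] + (x - s_pos[iL]) * ratio
  row <- as.data.frame(q, stringsAsFactors = FALSE)
  row$consensus_peak <- tr(peak)
  row$consensus_ci_lo <- tr(q$ci_lo_cM)
  row$consensus_ci_hi <- tr(q$ci_hi_cM)
  row$sigma <- (row$consensus_ci_hi - row$consensus_ci_lo) / 3.92
  row$anchor_lo <- common[iL]
  row$anchor_hi <- common[iR]
  row$scale_ratio <- ratio
  row$extrapolated <- extrapolated
  list(ok = TRUE, row = row)
}

#' Project a completed catalog onto the consensus map
#'
#' @param catalog a completed `qtl_catalog`.
#' @param maps named list of source [linkage_map()]s keyed by `study_id`.
#' @param cmap consensus map.
#' @param ratio_bounds see [project_qtl()].
#' @return list with `projected` (a `projected_qtl` data.frame, order
#'   stable) and `report` (totals and per-QTL rejection reasons).
#' @export
project_catalog <- function(catalog, maps, cmap, ratio_bounds = c(0.1, 10)) {
  stopifnot(inherits(catalog, "qtl_catalog"))
  unresolved <- setdiff(unique(catalog$study_id), names(maps))
  if (length(unresolved)) {
    stop_metaqtl("metaqtl_config_error",
                 "no source map for study id(s): %s",
                 paste(unresolved, collapse = ", "))
  }
  rows <- list()
  reasons <- character(0)
  for (i in seq_len(nrow(catalog))) {
    q <- catalog[i, ]
    res <- project_qtl(q, maps[[q$study_id]], cmap, ratio_bounds)
    if (res$ok) {
      rows[[length(rows) + 1]] <- res$row
    } else {
      reasons[q$qtl_id] <- res$reason
    }
  }
  projected <- if (length(rows)) do.call(rbind, rows) else
    cbind(as.data.frame(catalog)[0, ],
          consensus_peak = numeric(0), consensus_ci_lo = numeric(0),
          consensus_ci_hi = numeric(0), sigma = numeric(0),
          anchor_lo = character(0), anchor_hi = character(0),
          scale_ratio = numeric(0), extrapolated = logical(0))
  rownames(projected) <- NULL
  class(projected) <- c("projected_qtl", "data.frame")
  report <- list(
    n_input = nrow(catalog),
    n_projected = nrow(projected),
    n_rejected = length(reasons),
    reasons = reasons,
    reason_counts = as.list(table(factor(reasons, levels = REJECTION_CODES)))
  )
  list(projected = projected, report = report)
}

#' Write projected QTLs to TSV
#' @param projected a `projected_qtl` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_projected <- function(projected, path) {
  write_tsv(as.data.frame(projected), path)
}
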