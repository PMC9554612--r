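# QTL compendium: data model, validation, completion and summaries.
#
# A catalog is a data.frame with one row per initial QTL:
#   qtl_id, study_id, pop_type, pop_size, chr, flank_lo, flank_hi,
#   peak_cM, ci_lo_cM, ci_hi_cM, lod, pve_pct
# Empty cells mean "missing"; completion fills them by the compendium rules.

CATALOG_COLUMNS <- c("qtl_id", "study_id", "pop_type", "pop_size", "chr",
                     "flank_lo", "flank_hi", "peak_cM", "ci_lo_cM",
                     "ci_hi_cM", "lod", "pve_pct")

POP_TYPES <- c("RIL", "DH", "F2", "BC", "NIL")

# 95% CI width constants from simulation studies of mapping precision:
# backcross/F2 530, doubled haploids 287, recombinant inbreds 163. NILs
# derive from inbred lines and use the RIL constant.
CI_CONSTANTS <- c(F2 = 530, BC = 530, DH = 287, RIL = 163, NIL = 163)

#' Read a QTL compendium table
#'
#' Loads a tab-separated QTL compendium (one row per initial QTL reported by
#' a mapping study) and validates it. Duplicate `qtl_id`s are made unique by
#' suffixing (`.2`, `.3`, ...) and recorded in the `"relabelled"` attribute.
#'
#' @param path path to a TSV file with the columns `qtl_id`, `study_id`,
#'   `pop_type`, `pop_size`, `chr`, `flank_lo`, `flank_hi`, `peak_cM`,
#'   `ci_lo_cM`, `ci_hi_cM`, `lod`, `pve_pct`. Empty cells are missing
#'   values.
#' @return a validated `qtl_catalog` data.frame, row order preserved.
#' @seealso [complete_catalog()], [summarize_catalog()]
#' @export
read_qtl_catalog <- function(path) {
  df <- read_tsv_strict(path, required = CATALOG_COLUMNS)
  as_qtl_catalog(df)
}

#' Coerce and validate a QTL catalog
#'
#' @param df data.frame with the catalog columns (see [read_qtl_catalog()]).
#' @return a `qtl_catalog` data.frame.
#' @export
as_qtl_catalog <- function(df) {
  missing <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing)) {
    stop_metaqtl("metaqtl_schema_error", "missing required column(s): %s",
                 paste(missing, collapse = ", "))
  }
  df <- df[, CATALOG_COLUMNS]
  for (col in c("pop_size", "peak_cM", "ci_lo_cM", "ci_hi_cM", "lod",
                "pve_pct")) {
    val <- df[[col]]
    if (!is.numeric(val)) {
      conv <- suppressWarnings(as.numeric(val))
      bad <- which(!is.na(val) & is.na(conv) & val != "")
      if (length(bad)) {
        stop_metaqtl("metaqtl_row_error",
                     "non-numeric value in column '%s' at row %d", col,
                     bad[1])
      }
      df[[col]] <- conv
    }
  }
  for (col in c("qtl_id", "study_id", "pop_type", "chr", "flank_lo",
                "flank_hi")) {
    df[[col]] <- as.character(df[[col]])
  }
  validate_catalog_rows(df)
  relabelled <- character(0)
  if (anyDuplicated(df$qtl_id)) {
    dup <- duplicated(df$qtl_id)
    new_ids <- make.unique(df$qtl_id, sep = ".")
    relabelled <- new_ids[dup]
    df$qtl_id <- new_ids
  }
  structure(df, class = c("qtl_catalog", "data.frame"),
            relabelled = relabelled)
}

validate_catalog_rows <- function(df) {
  check_row <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad)) {
      stop_metaqtl("metaqtl_row_error", "row %d: %s", bad[1], msg)
    }
  }
  check_row(is.na(df$chr) | df$chr == "", "chromosome label is empty")
  check_row(!is.na(df$pop_type) & !(df$pop_type %in% POP_TYPES),
            sprintf("pop_type must be one of %s",
                    paste(POP_TYPES, collapse = "/")))
  check_row(!is.na(df$pop_size) & df$pop_size < 2, "population size < 2")
  check_row(!is.na(df$pve_pct) & (df$pve_pct <= 0 | df$pve_pct > 100),
            "PVE must be in (0, 100]")
  check_row(!is.na(df$lod) & df$lod < 0, "LOD must be >= 0")
  check_row(!is.na(df$peak_cM) & df$peak_cM < 0, "peak position must be >= 0")
  check_row(!is.na(df$ci_lo_cM) & !is.na(df$ci_hi_cM) &
              df$ci_lo_cM > df$ci_hi_cM, "ci_lo > ci_hi")
  invisible(df)
}

#' 95\% confidence-interval width for a detected QTL
#'
#' Population-specific approximation of the 95\% CI width of a QTL position:
#' `constant / (N * R2)` with constant 530 for F2/backcross, 287 for doubled
#' haploids and 163 for recombinant inbred lines (NILs use the RIL constant).
#'
#' @param pop_type one of `"RIL"`, `"DH"`, `"F2"`, `"BC"`, `"NIL"`.
#' @param n_ind number of individuals in the mapping population (>= 2).
#' @param r2 proportion of phenotypic variance explained, in (0, 1]. Note:
#'   a *fraction*, not the percent stored in the catalog.
#' @return CI width in cM.
#' @examples
#' estimate_ci("RIL", 163, 0.10)  # 10 cM
#' @export
estimate_ci <- function(pop_type, n_ind, r2) {
  pop_type <- match.arg(pop_type, POP_TYPES)
  if (any(n_ind < 2)) stop_metaqtl("metaqtl_domain_error", "N must be >= 2")
  if (any(r2 <= 0) || any(r2 > 1)) {
    stop_metaqtl("metaqtl_domain_error", "R2 must be in (0, 1]")
  }
  unname(CI_CONSTANTS[[pop_type]] / (n_ind * r2))
}

#' Complete missing fields of a QTL catalog
#'
#' Applies the compendium completion rules: a missing peak becomes the
#' midpoint of the two flanking markers (looked up on the record's source
#' map); a missing LOD becomes the reporting threshold 3.0; a missing CI is
#' the population-specific [estimate_ci()] width centred on the peak.
#' Already-present values are never overwritten. Records lacking both a peak
#' and resolvable flanking positions are dropped and recorded in the
#' `"excluded"` attribute (they correspond to non-projectable QTLs).
#'
#' @param catalog a `qtl_catalog`.
#' @param maps named list of [linkage_map()] objects keyed by `study_id`
#'   (used to resolve flanking-marker positions); may be `NULL` when every
#'   record already has a peak.
#' @param default_lod LOD assigned when a study reported none (default 3.0).
#' @return a completed `qtl_catalog`; attribute `"excluded"` lists dropped
#'   qtl_ids.
#' @export
complete_catalog <- function(catalog, maps = NULL, default_lod = 3.0) {
  stopifnot(inherits(catalog, "qtl_catalog"))
  excluded <- character(0)
  keep <- rep(TRUE, nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    if (is.na(rec$peak_cM)) {
      pos <- flank_positions(rec, maps)
      if (is.null(pos)) {
        keep[i] <- FALSE
        excluded <- c(excluded, rec$qtl_id)
        next
      }
      catalog$peak_cM[i] <- mean(pos)
    }
    if (is.na(catalog$lod[i])) catalog$lod[i] <- default_lod
    no_ci <- is.na(catalog$ci_lo_cM[i]) || is.na(catalog$ci_hi_cM[i]) ||
      catalog$ci_lo_cM[i] >= catalog$ci_hi_cM[i]
    if (no_ci) {
      if (is.na(catalog$pve_pct[i]) || is.na(catalog$pop_size[i]) ||
          is.na(catalog$pop_type[i])) {
        keep[i] <- FALSE
        excluded <- c(excluded, catalog$qtl_id[i])
        next
      }
      w <- estimate_ci(catalog$pop_type[i], catalog$pop_size[i],
                       catalog$pve_pct[i] / 100)
      catalog$ci_lo_cM[i] <- max(0, catalog$peak_cM[i] - w / 2)
      catalog$ci_hi_cM[i] <- catalog$peak_cM[i] + w / 2
    } else {
      # clamp a reported CI that fails to bracket the (possibly inferred) peak
      catalog$ci_lo_cM[i] <- min(catalog$ci_lo_cM[i], catalog$peak_cM[i])
      catalog$ci_hi_cM[i] <- max(catalog$ci_hi_cM[i], catalog$peak_cM[i])
    }
  }
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(catalog), excluded = excluded,
            completed = TRUE)
}

flank_positions <- function(rec, maps) {
  if (is.null(maps)) return(NULL)
  m <- maps[[rec$study_id]]
  if (is.null(m)) return(NULL)
  seg <- m[m$chr == rec$chr, ]
  lo <- seg$position_cM[match(tolower(rec$flank_lo), tolower(seg$marker))]
  hi <- seg$position_cM[match(tolower(rec$flank_hi), tolower(seg$marker))]
  if (length(lo) != 1 || length(hi) != 1 || is.na(lo) || is.na(hi)) {
    return(NULL)
  }
  c(lo, hi)
}

#' Summarize a QTL catalog
#'
#' Deterministic counts used for compendium overviews: per-chromosome and
#' per-sub-genome QTL counts, plus the standard CI (<5, 5-20, >20 cM), LOD
#' (<=10, >10) and PVE (<10, 10-20, >20 percent) bins.
#'
#' @param catalog a (preferably completed) `qtl_catalog`.
#' @return a list of class `catalog_summary`.
#' @export
summarize_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "qtl_catalog"))
  n <- nrow(catalog)
  ci_w <- catalog$ci_hi_cM - catalog$ci_lo_cM
  bins <- function(x, cuts, labels) {
    if (n == 0) return(stats::setNames(rep(0L, length(labels)), labels))
    stats::setNames(as.integer(table(cut(x, cuts, labels = labels,
                                         right = FALSE))), labels)
  }
  by_chr <- if (n) table(catalog$chr) else table(character(0))
  sg <- subgenome(catalog$chr)
  by_sub <- vapply(c("A", "B", "D"), function(s) sum(sg == s, na.rm = TRUE),
                   integer(1))
  out <- list(
    n = n,
    by_chromosome = as.list(by_chr),
    by_subgenome = as.list(by_sub),
    ci_bins = bins(ci_w, c(-Inf, 5, 20, Inf), c("<5", "5-20", ">20")),
    lod_bins = bins(catalog$lod, c(-Inf, 10 + 1e-12, Inf), c("<=10", ">10")),
    pve_bins = bins(catalog$pve_pct, c(-Inf, 10, 20 + 1e-12, Inf),
                    c("<10", "10-20", ">20"))
  )
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("QTL catalog:", x$n, "records\n")
  cat("  sub-genomes A/B/D:",
      paste(unlist(x$by_subgenome), collapse = "/"), "\n")
  cat("  CI bins <5 / 5-20 / >20 cM:",
      paste(x$ci_bins, collapse = " / "), "\n")
  cat("  PVE bins <10 / 10-20 / >20 %:",
      paste(x$pve_bins, collapse = " / "), "\n")
  invisible(x)
}

#' Write a QTL catalog to TSV
#' @param catalog a `qtl_catalog`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_qtl_catalog <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path)
}
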