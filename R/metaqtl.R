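# Meta-QTL delineation: per-chromosome mixture fits, model selection, and
# construction of consensus regions (meta-QTLs vs hotspots vs singletons).

REGION_COLUMNS <- c("mqtl_id", "chr", "position", "ci_lo", "ci_hi",
                    "ci_width", "flank_lo", "flank_hi", "n_qtls",
                    "n_studies", "avg_lod", "avg_pve", "class")

#' Build meta-QTL regions from a mixture fit
#'
#' Each projected QTL is assigned to its max-posterior component. Per
#' component the consensus position is the precision-weighted (1/s_i^2)
#' mean of member peaks, its variance `1/sum(1/s_i^2)`, and the 95% CI
#' `position +/- 1.96 * sqrt(var)`. Members whose peak falls outside that
#' CI are moved to the non-supporting set and the component is recomputed
#' once (a single refinement pass). Components left with one member are
#' singletons; the rest are classed `MQTL` (members from >= 2 studies) or
#' `HOTSPOT` (single study).
#'
#' @param fit a `qtl_mixture` fitted to the chromosome's projected peaks.
#' @param members the `projected_qtl` rows the fit was computed from (same
#'   order as `fit$x`).
#' @param chromosome chromosome label.
#' @param cmap optional consensus map used to attach the nearest flanking
#'   markers outside each region CI.
#' @return list with `regions` (data.frame), `singletons` and
#'   `non_supporting` (qtl_id vectors), and `assignment`.
#' @export
build_metaqtls <- function(fit, members, chromosome, cmap = NULL) {
  stopifnot(inherits(fit, "qtl_mixture"), nrow(members) == fit$n)
  assign <- max.col(fit$resp, ties.method = "first")
  singletons <- character(0)
  non_supporting <- character(0)
  comps <- list()
  for (k in sort(unique(assign))) {
    idx <- which(assign == k)
    stats_k <- ivw_mean(members$consensus_peak[idx], members$sigma[idx]^2)
    ci <- stats_k$mean + c(-1, 1) * 1.96 * sqrt(stats_k$var)
    # support check: a member's peak must be statistically consistent with
    # the component, i.e. inside its own 95% predictive interval around the
    # consensus position (mean CI alone shrinks as 1/sqrt(n) and would
    # reject typical members of large components)
    dev <- abs(members$consensus_peak[idx] - stats_k$mean)
    outside <- dev > 1.96 * sqrt(stats_k$var + members$sigma[idx]^2)
    if (any(outside) && !all(outside)) {      # one refinement pass
      non_supporting <- c(non_supporting, members$qtl_id[idx[outside]])
      idx <- idx[!outside]
      stats_k <- ivw_mean(members$consensus_peak[idx], members$sigma[idx]^2)
      ci <- stats_k$mean + c(-1, 1) * 1.96 * sqrt(stats_k$var)
    }
    if (length(idx) == 1) {
      singletons <- c(singletons, members$qtl_id[idx])
      next
    }
    comps[[length(comps) + 1]] <- list(idx = idx, position = stats_k$mean,
                                       ci = ci)
  }
  if (!length(comps)) {
    return(list(regions = empty_regions(), singletons = singletons,
                non_supporting = non_supporting, assignment = assign))
  }
  ord <- order(vapply(comps, function(cp) cp$position, numeric(1)))
  comps <- comps[ord]
  rows <- lapply(comps, function(cp) {
    mem <- members[cp$idx, ]
    n_studies <- length(unique(mem$study_id))
    flk <- nearest_flanks(cmap, chromosome, cp$ci)
    data.frame(
      mqtl_id = NA_character_, chr = chromosome, position = cp$position,
      ci_lo = cp$ci[1], ci_hi = cp$ci[2], ci_width = diff(cp$ci),
      flank_lo = flk[1], flank_hi = flk[2],
      n_qtls = nrow(mem), n_studies = n_studies,
      avg_lod = mean(mem$lod), avg_pve = mean(mem$pve_pct),
      class = if (n_studies >= 2) "MQTL" else "HOTSPOT",
      stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  regions$mqtl_id <- region_names(regions, chromosome)
  members_of <- lapply(comps, function(cp) members$qtl_id[cp$idx])
  names(members_of) <- regions$mqtl_id
  list(regions = regions, singletons = singletons,
       non_supporting = non_supporting, assignment = assign,
       members_of = members_of)
}

empty_regions <- function() {
  df <- data.frame(mqtl_id = character(0), chr = character(0),
                   position = numeric(0), ci_lo = numeric(0),
                   ci_hi = numeric(0), ci_width = numeric(0),
                   flank_lo = character(0), flank_hi = character(0),
                   n_qtls = integer(0), n_studies = integer(0),
                   avg_lod = numeric(0), avg_pve = numeric(0),
                   class = character(0), stringsAsFactors = FALSE)
  df
}

region_names <- function(regions, chromosome) {
  out <- character(nrow(regions))
  is_m <- regions$class == "MQTL"
  out[is_m] <- sprintf("MQTL%s.%d", chromosome, seq_len(sum(is_m)))
  if (sum(!is_m) == 1) {
    out[!is_m] <- sprintf("QTLhotspot_%s", chromosome)
  } else if (sum(!is_m) > 1) {
    out[!is_m] <- sprintf("QTLhotspot_%s.%d", chromosome,
                          seq_len(sum(!is_m)))
  }
  out
}

nearest_flanks <- function(cmap, chromosome, ci) {
  if (is.null(cmap)) return(c(NA_character_, NA_character_))
  seg <- map_chromosome(cmap, chromosome)
  if (!nrow(seg)) return(c(NA_character_, NA_character_))
  below <- seg[seg$position_cM < ci[1], ]
  above <- seg[seg$position_cM > ci[2], ]
  lo <- if (nrow(below)) below$marker[which.max(below$position_cM)]
        else seg$marker[which.min(seg$position_cM)]
  hi <- if (nrow(above)) above$marker[which.min(above$position_cM)]
        else seg$marker[which.max(seg$position_cM)]
  c(lo, hi)
}

#' Meta-QTL analysis of projected QTLs
#'
#' The top-level fitting function. Per chromosome it fits Gaussian mixtures
#' with K = 1..Kmax components ([fit_qtl_mixture()]), picks K by the
#' five-criterion vote ([select_model()]), and builds consensus regions
#' ([build_metaqtls()]).
#'
#' @param projected a `projected_qtl` data.frame from [project_catalog()].
#' @param cmap consensus map (for flanking-marker annotation); optional.
#' @param Kmax maximum component count considered (capped at the number of
#'   QTLs on the chromosome); default 10.
#' @param n_restarts,seed EM restart control, see [fit_qtl_mixture()].
#' @return an object of class `meta_qtl` with fields `regions` (data.frame
#'   with one row per MQTL/hotspot), `singletons`, `non_supporting`,
#'   `members_of`, `selection` (per-chromosome criteria tables),
#'   `projected`, and `call`.
#' @examples
#' \donttest{
#' sc <- synthetic_scenario(seed = 1)
#' res <- meta_pipeline(sc$catalog, sc$maps, seed = 1)
#' print(res$fit)
#' }
#' @export
meta_qtl <- function(projected, cmap = NULL, Kmax = 10, n_restarts = 5,
                     seed = 1) {
  stopifnot(is.data.frame(projected))
  chrs <- sort(unique(projected$chr))
  regions <- list(); singletons <- character(0)
  non_supporting <- character(0); selection <- list()
  members_of <- list()
  for (ch in chrs) {
    mem <- projected[projected$chr == ch, , drop = FALSE]
    n <- nrow(mem)
    kmax_ch <- min(n, Kmax)
    fits <- lapply(seq_len(kmax_ch), function(k)
      fit_qtl_mixture(mem$consensus_peak, mem$sigma^2, k,
                      n_restarts = n_restarts,
                      seed = derive_seed(seed, match(ch, chrs))))
    sel <- select_model(fits)
    built <- build_metaqtls(fits[[sel$K]], mem, ch, cmap)
    regions[[ch]] <- built$regions
    singletons <- c(singletons, built$singletons)
    non_supporting <- c(non_supporting, built$non_supporting)
    members_of <- c(members_of, built$members_of)
    selection[[ch]] <- sel
  }
  regions <- do.call(rbind, c(regions, list(empty_regions())))
  rownames(regions) <- NULL
  structure(list(regions = regions, singletons = singletons,
                 non_supporting = non_supporting, members_of = members_of,
                 selection = selection, projected = projected,
                 call = match.call()),
            class = "meta_qtl")
}

#' @export
print.meta_qtl <- function(x, ...) {
  cat("Meta-QTL analysis\n")
  cat(sprintf("  %d projected QTLs on %d chromosome(s)\n",
              nrow(x$projected), length(unique(x$projected$chr))))
  cat(sprintf("  %d regions (%d MQTLs, %d hotspots), %d singletons, %d non-supporting\n",
              nrow(x$regions), sum(x$regions$class == "MQTL"),
              sum(x$regions$class == "HOTSPOT"), length(x$singletons),
              length(x$non_supporting)))
  invisible(x)
}

#' @export
coef.meta_qtl <- function(object, ...) object$regions

#' @export
summary.meta_qtl <- function(object, ...) {
  s <- summarize_regions(object$regions, object$projected)
  s$n_singletons <- length(object$singletons)
  s$n_non_supporting <- length(object$non_supporting)
  class(s) <- "summary.meta_qtl"
  s
}

#' @export
print.summary.meta_qtl <- function(x, ...) {
  cat("Meta-QTL summary\n")
  cat(sprintf("  regions: %d (MQTL %d / hotspot %d)\n", x$n_regions,
              x$class_counts[["MQTL"]], x$class_counts[["HOTSPOT"]]))
  cat(sprintf("  CI width (cM): min %.2f / mean %.2f / max %.2f\n",
              x$ci$min, x$ci$mean, x$ci$max))
  if (is.finite(x$fold_reduction)) {
    cat(sprintf("  CI fold reduction vs initial QTLs: %.2f\n",
                x$fold_reduction))
  }
  cat(sprintf("  member bins =2 / 3-4 / >=5: %s\n",
              paste(x$member_bins, collapse = " / ")))
  invisible(x)
}

#' @export
plot.meta_qtl <- function(x, ...) {
  reg <- x$regions
  if (!nrow(reg)) return(invisible(x))
  chrs <- unique(reg$chr)
  ypos <- match(reg$chr, chrs)
  graphics::plot(NA, xlim = range(c(reg$ci_lo, reg$ci_hi)),
                 ylim = c(0.5, length(chrs) + 0.5), yaxt = "n",
                 xlab = "consensus position (cM)", ylab = "",
                 main = "Meta-QTL regions", ...)
  graphics::axis(2, at = seq_along(chrs), labels = chrs, las = 1)
  graphics::segments(reg$ci_lo, ypos, reg$ci_hi, ypos,
                     col = ifelse(reg$class == "MQTL", "steelblue",
                                  "firebrick"), lwd = 3)
  graphics::points(reg$position, ypos, pch = 19)
  invisible(x)
}

#' Summary statistics over meta-QTL regions
#'
#' @param regions region data.frame (as in `meta_qtl()$regions` or the
#'   packaged region tables).
#' @param projected optional `projected_qtl` data.frame; when given, the
#'   CI fold reduction `mean(initial widths) / mean(region widths)` is
#'   computed.
#' @return list with counts, CI/LOD/PVE ranges, member-count bins and the
#'   fold reduction (`NA` when not computable).
#' @export
summarize_regions <- function(regions, projected = NULL) {
  n <- nrow(regions)
  rng <- function(v) list(min = if (n) min(v) else NA_real_,
                          max = if (n) max(v) else NA_real_,
                          mean = if (n) mean(v) else NA_real_)
  fold <- NA_real_
  if (!is.null(projected) && n > 0 && nrow(projected) > 0) {
    init_w <- projected$consensus_ci_hi - projected$consensus_ci_lo
    fold <- mean(init_w) / mean(regions$ci_width)
  }
  sg <- subgenome(regions$chr)
  list(
    n_regions = n,
    class_counts = list(
      MQTL = sum(regions$class == "MQTL"),
      HOTSPOT = sum(regions$class == "HOTSPOT")),
    by_chromosome = as.list(table(regions$chr)),
    by_subgenome = vapply(c("A", "B", "D"),
                          function(s) sum(sg == s, na.rm = TRUE),
                          integer(1)),
    ci = rng(regions$ci_width),
    avg_lod = rng(regions$avg_lod),
    avg_pve = rng(regions$avg_pve),
    member_bins = c(
      "=2" = sum(regions$n_qtls == 2),
      "3-4" = sum(regions$n_qtls %in% c(3, 4)),
      ">=5" = sum(regions$n_qtls >= 5)),
    fold_reduction = fold
  )
}

#' Fold reduction in the number of trait-associated loci
#'
#' Ratio of projected initial QTLs to consensus regions; the headline
#' "how much did meta-analysis condense the genetic architecture" number.
#'
#' @param n_projected number of initial QTLs successfully projected.
#' @param n_regions number of consensus regions (MQTLs + hotspots).
#' @return the ratio, as a plain number.
#' @export
qtl_reduction_factor <- function(n_projected, n_regions) {
  if (n_regions <= 0) {
    stop_metaqtl("metaqtl_domain_error", "n_regions must be positive")
  }
  n_projected / n_regions
}

#' Write a region table to TSV
#' @param regions region data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regions <- function(regions, path) {
  write_tsv(regions, path)
}
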