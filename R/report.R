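# Breeders'-MQTL filtering and region-table reporting.

#' Breeders'-MQTL selection criteria
#'
#' Thresholds for picking regions directly usable in marker-assisted
#' breeding: narrow CI, sizeable effect, solid support, and evidence from
#' several studies. Comparisons are strict for CI/PVE/LOD ("less than" /
#' "more than") and inclusive for the member count ("at least").
#'
#' @param max_ci maximum CI width in cM (strict <, default 2.5).
#' @param min_pve minimum average PVE percent (strict >, default 10).
#' @param min_lod minimum average LOD (strict >, default 3.5).
#' @param min_members minimum number of member QTLs (>=, default 3).
#' @param require_multi_study drop single-study regions (hotspots);
#'   default TRUE.
#' @return list of class `breeder_criteria`.
#' @export
breeder_criteria <- function(max_ci = 2.5, min_pve = 10, min_lod = 3.5,
                             min_members = 3, require_multi_study = TRUE) {
  stopifnot(max_ci > 0, min_pve > 0, min_lod > 0, min_members > 0)
  structure(list(max_ci = max_ci, min_pve = min_pve, min_lod = min_lod,
                 min_members = min_members,
                 require_multi_study = require_multi_study),
            class = "breeder_criteria")
}

#' Select breeders' MQTLs from a region table
#'
#' @param regions region data.frame (`ci_width`, `avg_pve`, `avg_lod`,
#'   `n_qtls`, `class` columns).
#' @param criteria a [breeder_criteria()] object.
#' @return character vector of selected region ids (table order).
#' @export
breeders_filter <- function(regions, criteria = breeder_criteria()) {
  stopifnot(inherits(criteria, "breeder_criteria"))
  keep <- regions$ci_width < criteria$max_ci &
    regions$avg_pve > criteria$min_pve &
    regions$avg_lod > criteria$min_lod &
    regions$n_qtls >= criteria$min_members
  if (criteria$require_multi_study) {
    keep <- keep & regions$class == "MQTL"
  }
  regions$mqtl_id[keep]
}

#' Region-table report
#'
#' Deterministic summary of a region table: class and chromosome counts,
#' member-count bins, CI/LOD/PVE ranges, and the cross-tabulation of the
#' four breeders' criteria.
#'
#' @param regions region data.frame.
#' @param criteria [breeder_criteria()] used for the cross-tab.
#' @return list of class `region_report`.
#' @export
region_report <- function(regions, criteria = breeder_criteria()) {
  s <- summarize_regions(regions)
  crit_tab <- if (nrow(regions)) {
    data.frame(
      criterion = c(sprintf("CI < %g cM", criteria$max_ci),
                    sprintf("PVE > %g%%", criteria$min_pve),
                    sprintf("LOD > %g", criteria$min_lod),
                    sprintf(">= %d members", criteria$min_members)),
      n = c(sum(regions$ci_width < criteria$max_ci),
            sum(regions$avg_pve > criteria$min_pve),
            sum(regions$avg_lod > criteria$min_lod),
            sum(regions$n_qtls >= criteria$min_members)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(criterion = character(0), n = integer(0))
  }
  out <- c(s, list(criteria_crosstab = crit_tab,
                   breeders_mqtls = breeders_filter(regions, criteria)))
  class(out) <- "region_report"
  out
}

#' @export
print.region_report <- function(x, ...) {
  cat("Region report:", x$n_regions, "regions",
      sprintf("(MQTL %d / hotspot %d)\n", x$class_counts$MQTL,
              x$class_counts$HOTSPOT))
  if (x$n_regions == 0) return(invisible(x))
  cat(sprintf("  CI width (cM): %.2f-%.2f (mean %.2f)\n", x$ci$min,
              x$ci$max, x$ci$mean))
  cat(sprintf("  avg LOD: %.2f-%.2f; avg PVE: %.2f-%.2f%%\n",
              x$avg_lod$min, x$avg_lod$max, x$avg_pve$min, x$avg_pve$max))
  cat(sprintf("  member bins =2 / 3-4 / >=5: %s\n",
              paste(x$member_bins, collapse = " / ")))
  cat("  breeders' MQTLs:", if (length(x$breeders_mqtls))
    paste(x$breeders_mqtls, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write a region report as JSON
#' @param report a `region_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write a region report as Markdown
#' @param report a `region_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_md <- function(report, path) {
  lines <- c(
    "# Meta-QTL region report", "",
    sprintf("- regions: %d (MQTL %d, hotspot %d)", report$n_regions,
            report$class_counts$MQTL, report$class_counts$HOTSPOT))
  if (report$n_regions > 0) {
    lines <- c(lines,
      sprintf("- CI width (cM): %.2f to %.2f, mean %.2f", report$ci$min,
              report$ci$max, report$ci$mean),
      sprintf("- average LOD: %.2f to %.2f", report$avg_lod$min,
              report$avg_lod$max),
      sprintf("- average PVE (%%): %.2f to %.2f", report$avg_pve$min,
              report$avg_pve$max),
      sprintf("- member bins (=2 / 3-4 / >=5): %s",
              paste(report$member_bins, collapse = " / ")),
      "", "## Breeders' MQTLs", "",
      if (length(report$breeders_mqtls))
        paste0("- ", report$breeders_mqtls) else "- none")
  }
  writeLines(lines, path)
  invisible(path)
}
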