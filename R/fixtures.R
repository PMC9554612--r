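# Packaged region tables: the published wheat grain-protein-content
# MQTL and QTL-hotspot tables, transcribed with their printed columns.

#' Published wheat GPC meta-QTL region table
#'
#' Loads the packaged transcription of the published grain-protein-content
#' meta-QTL table (57 MQTLs), the QTL-hotspot table (7 hotspots), or both
#' combined, in the package's standard region-table layout. Printed CI
#' widths are kept as `ci_width`; `ci_lo`/`ci_hi` are centred on the
#' printed position. `flank_lo`/`flank_hi` are the first and last of the
#' printed flanking markers; `n_studies` is not printed and is set to the
#' member count for MQTLs (multi-study by definition) and 1 for hotspots.
#'
#' @param which `"mqtl"`, `"hotspot"` or `"both"`.
#' @return a region data.frame (see [meta_qtl()]).
#' @export
gpc_region_table <- function(which = c("both", "mqtl", "hotspot")) {
  which <- match.arg(which)
  load_one <- function(file, class) {
    path <- system.file("extdata", file, package = "metaqtl",
                        mustWork = TRUE)
    df <- read_tsv_strict(path, required = c("mqtl_id", "chr", "position",
                                             "ci_width", "flanking_markers",
                                             "n_qtls", "avg_lod", "avg_pve"))
    flk <- strsplit(df$flanking_markers, "/", fixed = TRUE)
    data.frame(
      mqtl_id = df$mqtl_id, chr = df$chr, position = df$position,
      ci_lo = df$position - df$ci_width / 2,
      ci_hi = df$position + df$ci_width / 2,
      ci_width = df$ci_width,
      flank_lo = vapply(flk, `[`, character(1), 1),
      flank_hi = vapply(flk, function(v) v[length(v)], character(1)),
      n_qtls = as.integer(df$n_qtls),
      n_studies = if (class == "MQTL") as.integer(df$n_qtls) else 1L,
      avg_lod = df$avg_lod, avg_pve = df$avg_pve, class = class,
      stringsAsFactors = FALSE)
  }
  out <- switch(which,
    mqtl = load_one("gpc_mqtl_table.tsv", "MQTL"),
    hotspot = load_one("gpc_hotspot_table.tsv", "HOTSPOT"),
    both = rbind(load_one("gpc_mqtl_table.tsv", "MQTL"),
                 load_one("gpc_hotspot_table.tsv", "HOTSPOT")))
  rownames(out) <- NULL
  out
}
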