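#' @keywords internal
"_PACKAGE"

# Shared helpers used across the pipeline modules.

#' Sub-genome of a wheat-style chromosome label
#'
#' The trailing letter of a chromosome label ("3A" -> "A") identifies the
#' sub-genome in allopolyploid wheat nomenclature.
#'
#' @param chr character vector of chromosome labels.
#' @return character vector of sub-genome letters; `NA` where the label does
#'   not end in a letter.
#' @export
subgenome <- function(chr) {
  out <- toupper(sub("^.*?([A-Za-z])$", "\\1", chr))
  out[!grepl("[A-Za-z]$", chr)] <- NA_character_
  out
}

# Inverse-variance weighted mean and its variance.
ivw_mean <- function(x, s2) {
  w <- 1 / s2
  list(mean = sum(w * x) / sum(w), var = 1 / sum(w))
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
stop_metaqtl <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "metaqtl_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer whatever small integer the user supplies.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647L)
}

# GRanges pair on a shared seqlevel universe (avoids spurious warnings
# when one side has chromosomes the other lacks).
granges_pair <- function(a_chr, a_start, a_end, b_chr, b_start, b_end) {
  lv <- unique(c(a_chr, b_chr))
  list(
    a = GenomicRanges::GRanges(
      factor(a_chr, levels = lv),
      IRanges::IRanges(a_start, a_end)),
    b = GenomicRanges::GRanges(
      factor(b_chr, levels = lv),
      IRanges::IRanges(b_start, b_end)))
}

read_tsv_strict <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop_metaqtl("metaqtl_schema_error",
                   "missing required column(s): %s",
                   paste(missing, collapse = ", "))
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
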