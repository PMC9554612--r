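# Candidate-gene extraction, expression filtering and known-gene
# co-localization.

genes_fixture <- function() {
  as_gene_models(data.frame(
    gene_id = c("g_in", "g_edge", "g_out", "g_far"),
    chr = c("1A", "1A", "1A", "2B"),
    start_bp = c(1.2e6, 0.9e6, 2.1e6, 1e6),
    end_bp = c(1.4e6, 1.0e6, 2.2e6, 1.1e6),
    description = "synthetic", stringsAsFactors = FALSE))
}

windows_fixture <- function() {
  data.frame(mqtl_id = c("M1", "M2"), chr = c("1A", "1A"),
             win_start_bp = c(1e6, 5e6), win_end_bp = c(2e6, 6e6),
             stringsAsFactors = FALSE)
}

regions_fixture <- function(n1 = 3L, n2 = 2L) {
  data.frame(mqtl_id = c("M1", "M2"), n_qtls = c(n1, n2),
             stringsAsFactors = FALSE)
}

test_that("window scan keeps overlapping genes of promising regions only", {
  hits <- genes_in_windows(genes_fixture(), windows_fixture(),
                           regions_fixture())
  # M2 has two members only: not scanned; edge overlap of 1 bp counts
  expect_setequal(hits$gene_id, c("g_in", "g_edge"))
  expect_true(all(hits$mqtl_id == "M1"))
  # with both regions promising, still nothing in M2's empty window
  hits2 <- genes_in_windows(genes_fixture(), windows_fixture(),
                            regions_fixture(3L, 5L))
  expect_setequal(hits2$gene_id, c("g_in", "g_edge"))
})

test_that("window scan agrees with the all-pairs oracle on random data", {
  set.seed(23)
  for (i in 1:5) {
    ng <- 40
    genes <- as_gene_models(data.frame(
      gene_id = sprintf("g%02d", 1:ng),
      chr = sample(c("1A", "2B"), ng, replace = TRUE),
      start_bp = s <- round(runif(ng, 1, 5e6)),
      end_bp = s + round(runif(ng, 1e3, 5e4)),
      description = "", stringsAsFactors = FALSE))
    win <- data.frame(mqtl_id = c("M1", "M2"),
                      chr = sample(c("1A", "2B"), 2, replace = TRUE),
                      win_start_bp = w <- round(runif(2, 1, 4e6)),
                      win_end_bp = w + 5e5)
    reg <- data.frame(mqtl_id = c("M1", "M2"), n_qtls = c(4L, 4L))
    hits <- genes_in_windows(genes, win, reg)
    oracle <- overlap_oracle(win$chr, win$win_start_bp, win$win_end_bp,
                             genes$chr, genes$start_bp, genes$end_bp)
    expect_equal(nrow(hits), sum(oracle))
  }
})

test_that("expression filter is strict at the threshold and warns on misses", {
  hits <- genes_in_windows(genes_fixture(), windows_fixture(),
                           regions_fixture())
  tissues <- c(grain_1 = "grain", root_1 = "root")
  expr <- data.frame(grain_1 = c(2.0, 5), root_1 = c(50, 0.1),
                     row.names = c("g_in", "g_edge"))
  kept <- filter_expressed(hits, expr, tissues)
  # g_in: TPM exactly 2 in grain (excluded, strict >), 50 in root
  # (irrelevant tissue); g_edge: 5 in grain -> kept
  expect_equal(kept$gene_id, "g_edge")

  # gene absent from the matrix: excluded with a warning
  expr2 <- expr["g_edge", , drop = FALSE]
  expect_warning(kept2 <- filter_expressed(hits, expr2, tissues),
                 "absent")
  expect_equal(kept2$gene_id, "g_edge")
  expect_error(filter_expressed(hits, expr, tissues, relevant = character(0)),
               class = "metaqtl_config_error")
})

test_that("raising the TPM threshold never adds genes", {
  set.seed(29)
  ids <- sprintf("g%02d", 1:30)
  hits <- data.frame(mqtl_id = "M1", gene_id = ids, chr = "1A",
                     start_bp = 1, end_bp = 2, description = "")
  tissues <- c(s1 = "grain", s2 = "spike")
  expr <- data.frame(s1 = rlnorm(30, 0, 1.5), s2 = rlnorm(30, 0, 1.5),
                     row.names = ids)
  prev <- NULL
  for (thr in c(0.5, 1, 2, 4, 8)) {
    kept <- filter_expressed(hits, expr, tissues, tpm_threshold = thr)
    if (!is.null(prev)) expect_true(all(kept$gene_id %in% prev))
    prev <- kept$gene_id
  }
  # the filtered set is always a subset of the window genes
  expect_true(all(prev %in% hits$gene_id))
})

test_that("known genes co-localize by full-interval overlap", {
  iv <- data.frame(mqtl_id = "M1", chr = "1A", start_bp = 1e6,
                   end_bp = 2e6, span_bp = 1e6, peak_bp = 1.5e6,
                   anchored = TRUE, degenerate = FALSE, provenance = "",
                   stringsAsFactors = FALSE)
  known <- as_gene_models(data.frame(
    gene_id = c("inside", "outside"), chr = "1A",
    start_bp = c(1.5e6, 2e6 + 2), end_bp = c(1.6e6, 2.1e6),
    description = "", stringsAsFactors = FALSE))
  res <- known_gene_colocalization(known, iv)
  expect_equal(res$gene_id, "inside")
  expect_equal(nrow(known_gene_colocalization(known[0, ], iv)), 0)
})

test_that("GFF3 gene features round-trip through the reader", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1A\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gene1;description=kinase",
    "1A\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=t1;Parent=gene1",
    "2B\ttest\tgene\t500\t900\t.\t-\t.\tID=gene2"), gff)
  g <- read_gene_models(gff)
  expect_equal(nrow(g), 2)
  expect_setequal(g$gene_id, c("gene1", "gene2"))
  expect_equal(g$start_bp[g$gene_id == "gene1"], 1000)
})
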