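# Synthetic multi-study generator: determinism, construction guarantees
# and validation layers.

test_that("generation is a pure function of (config, seed)", {
  cfg <- truth_config()
  a <- synthetic_scenario(cfg, seed = 4)
  b <- synthetic_scenario(cfg, seed = 4)
  expect_identical(a$truth$loci, b$truth$loci)
  expect_identical(as.data.frame(a$catalog), as.data.frame(b$catalog))
  expect_identical(a$expression, b$expression)
  c_ <- synthetic_scenario(cfg, seed = 5)
  expect_false(identical(a$truth$loci, c_$truth$loci))
})

test_that("true loci respect the minimum separation; zero loci allowed", {
  cfg <- truth_config(sigma_cM = 4)
  tr <- generate_truth(cfg, seed = 2)
  for (ch in unique(tr$loci$chr)) {
    pos <- sort(tr$loci$cM[tr$loci$chr == ch])
    if (length(pos) > 1) expect_gte(min(diff(pos)), 16)  # 4 * sigma
  }
  empty <- generate_truth(truth_config(n_true_loci = 0), seed = 1)
  expect_equal(nrow(empty$loci), 0)
  expect_error(
    generate_truth(truth_config(n_true_loci = 50, min_locus_gap_cM = 50),
                   seed = 1),
    class = "metaqtl_config_error")
})

test_that("detection counting is exact at p_det = 1 and binomial at 0.5", {
  cfg1 <- truth_config(p_det = 1, missing_peak = 0, missing_lod = 0,
                       missing_ci = 0)
  tr <- generate_truth(cfg1, seed = 1)
  st <- generate_studies(tr, seed = 1)
  expect_equal(nrow(st$catalog), 10 * nrow(tr$loci))

  cfg2 <- truth_config(
    chromosomes = data.frame(chr = "1A", len_cM = 200, len_bp = 4e8),
    n_true_loci = 1, n_studies = 200, p_det = 0.5, missing_peak = 0,
    missing_lod = 0, missing_ci = 0)
  tr2 <- generate_truth(cfg2, seed = 2)
  st2 <- generate_studies(tr2, seed = 2)
  n_det <- nrow(st2$catalog)
  expect_lt(abs(n_det - 100), 3 * sqrt(200 * 0.25))
})

test_that("every generated QTL's flanks bracket its peak on its study map", {
  sc <- synthetic_scenario(truth_config(missing_peak = 0, missing_lod = 0,
                                        missing_ci = 0), seed = 6)
  for (i in seq_len(nrow(sc$catalog))) {
    q <- sc$catalog[i, ]
    seg <- sc$maps[[q$study_id]]
    lo <- seg$position_cM[seg$marker == q$flank_lo & seg$chr == q$chr]
    hi <- seg$position_cM[seg$marker == q$flank_hi & seg$chr == q$chr]
    expect_lte(lo, q$peak_cM)
    expect_gte(hi, q$peak_cM)
  }
})

test_that("study maps are subsets of the master grid with a common scale", {
  sc <- synthetic_scenario(seed = 8)
  for (sid in names(sc$maps)) {
    m <- sc$maps[[sid]]
    expect_true(all(m$marker %in% sc$master$marker))
    # positions are the master positions times one per-study factor
    shared <- merge(as.data.frame(m), as.data.frame(sc$master),
                    by = c("chr", "marker"))
    nz <- shared$position_cM.y > 0
    ratio <- shared$position_cM.x[nz] / shared$position_cM.y[nz]
    expect_lt(diff(range(ratio)), 1e-9)
  }
})

test_that("the marker physical table is monotone within chromosomes", {
  sc <- synthetic_scenario(seed = 9)
  tab <- merge(sc$marker_table, as.data.frame(sc$master),
               by = c("marker", "chr"))
  for (ch in unique(tab$chr)) {
    seg <- tab[tab$chr == ch, ]
    seg <- seg[order(seg$position_cM), ]
    expect_true(all(diff(seg$bp) >= 0))
  }
})

test_that("planted validation layers are recoverable by construction", {
  cfg <- truth_config(mta_decoys_per_chr = 0)
  tr <- generate_truth(cfg, seed = 10)
  val <- generate_validation_layers(tr, seed = 10)
  # every MTA sits within the jitter radius of its true locus
  for (i in seq_len(nrow(val$mtas))) {
    locs <- tr$loci[tr$loci$chr == val$mtas$chr[i], ]
    expect_lte(min(abs(locs$bp - val$mtas$bp[i])), cfg$mta_jitter_bp)
  }
  # planted known genes co-localize with intervals centred on the truth
  iv <- data.frame(mqtl_id = paste0("T", seq_len(nrow(tr$loci))),
                   chr = tr$loci$chr, start_bp = tr$loci$bp - 1e6,
                   end_bp = tr$loci$bp + 1e6, span_bp = 2e6,
                   peak_bp = tr$loci$bp, anchored = TRUE,
                   degenerate = FALSE, provenance = "",
                   stringsAsFactors = FALSE)
  coloc <- known_gene_colocalization(val$known_genes, iv)
  expect_true(all(val$known_genes$gene_id %in% coloc$gene_id))
})

test_that("the expressed fraction is controlled, with zero as a hard off", {
  cfg0 <- truth_config(frac_expressed = 0)
  tr <- generate_truth(cfg0, seed = 11)
  val <- generate_validation_layers(tr, seed = 11)
  hits <- data.frame(mqtl_id = "M1", gene_id = val$genes$gene_id,
                     chr = val$genes$chr, start_bp = val$genes$start_bp,
                     end_bp = val$genes$end_bp, description = "")
  kept <- filter_expressed(hits, as.data.frame(val$expression),
                           val$tissues)
  expect_equal(nrow(kept), 0)

  cfg1 <- truth_config(frac_expressed = 1)
  val1 <- generate_validation_layers(generate_truth(cfg1, seed = 12),
                                     seed = 12)
  kept1 <- filter_expressed(
    data.frame(mqtl_id = "M1", gene_id = val1$genes$gene_id,
               chr = val1$genes$chr, start_bp = val1$genes$start_bp,
               end_bp = val1$genes$end_bp, description = ""),
    as.data.frame(val1$expression), val1$tissues)
  expect_equal(nrow(kept1), nrow(val1$genes))
})

test_that("scenario configs round-trip through YAML", {
  cfg <- truth_config(n_studies = 6, p_det = 0.9)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    chromosomes = list(list(chr = "1A", len_cM = 250, len_bp = 5e8)),
    n_studies = 6, p_det = 0.9), path)
  got <- read_scenario_config(path)
  expect_s3_class(got, "truth_config")
  expect_equal(got$n_studies, 6)
  expect_equal(got$chromosomes$chr, "1A")
  expect_equal(got$p_det, 0.9)
})
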