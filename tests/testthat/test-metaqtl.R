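# Region construction, classification and summaries.

projected_stub <- function(peaks, sigmas, studies, chr = "1A",
                           lod = NULL, pve = NULL) {
  n <- length(peaks)
  df <- data.frame(
    qtl_id = sprintf("q%d", seq_len(n)), study_id = studies,
    pop_type = "RIL", pop_size = 150, chr = chr, flank_lo = "A",
    flank_hi = "B", peak_cM = peaks, ci_lo_cM = peaks - 1.96 * sigmas,
    ci_hi_cM = peaks + 1.96 * sigmas, lod = lod %||% rep(4, n),
    pve_pct = pve %||% rep(10, n), consensus_peak = peaks,
    consensus_ci_lo = peaks - 1.96 * sigmas,
    consensus_ci_hi = peaks + 1.96 * sigmas, sigma = sigmas,
    anchor_lo = "A", anchor_hi = "B", scale_ratio = 1,
    extrapolated = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("projected_qtl", "data.frame")
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a two-member component gives the closed-form position and CI", {
  mem <- projected_stub(c(10, 11), c(1, 1), c("S1", "S2"))
  fit <- fit_qtl_mixture(mem$consensus_peak, mem$sigma^2, K = 1)
  built <- build_metaqtls(fit, mem, "1A")
  reg <- built$regions
  expect_equal(nrow(reg), 1)
  expect_equal(reg$position, 10.5)
  expect_equal(reg$ci_width, 2 * 1.96 * sqrt(0.5), tolerance = 1e-9)
  expect_equal(reg$class, "MQTL")
  expect_equal(reg$mqtl_id, "MQTL1A.1")
  expect_equal(reg$n_qtls, 2)
  expect_equal(reg$avg_lod, 4)
})

test_that("single-study components are hotspots, multi-study are MQTLs", {
  mem <- projected_stub(c(10, 11, 12), c(2, 2, 2), rep("S1", 3))
  fit <- fit_qtl_mixture(mem$consensus_peak, mem$sigma^2, K = 1)
  built <- build_metaqtls(fit, mem, "5D")
  expect_equal(built$regions$class, "HOTSPOT")
  expect_equal(built$regions$mqtl_id, "QTLhotspot_5D")
})

test_that("one-member components are emitted as singletons, not regions", {
  mem <- projected_stub(c(10, 11, 80), c(1, 1, 1), c("S1", "S2", "S3"))
  fit <- fit_qtl_mixture(mem$consensus_peak, mem$sigma^2, K = 2,
                         seed = 1)
  built <- build_metaqtls(fit, mem, "1A")
  expect_equal(nrow(built$regions), 1)
  expect_equal(built$singletons, "q3")
})

test_that("members inconsistent with their component are set aside once", {
  # nine tight members plus one 12 sigma away in the same component
  mem <- projected_stub(c(rep(30, 9), 42), rep(1, 10),
                        sprintf("S%d", 1:10))
  fit <- fit_qtl_mixture(mem$consensus_peak, mem$sigma^2, K = 1)
  built <- build_metaqtls(fit, mem, "1A")
  expect_equal(built$non_supporting, "q10")
  expect_equal(built$regions$n_qtls, 9)
  expect_equal(built$regions$position, 30, tolerance = 1e-6)
})

test_that("regions are numbered by position within the chromosome", {
  mem <- projected_stub(c(80, 81, 10, 11), c(1, 1, 1, 1),
                        c("S1", "S2", "S1", "S2"))
  fit <- fit_qtl_mixture(mem$consensus_peak, mem$sigma^2, K = 2, seed = 1)
  built <- build_metaqtls(fit, mem, "2B")
  expect_equal(built$regions$mqtl_id, c("MQTL2B.1", "MQTL2B.2"))
  expect_true(all(diff(built$regions$position) > 0))
})

test_that("flanking markers are the nearest consensus markers outside the CI", {
  cmap <- merge_maps(list(tiny_map("m", c(0, 5, 9.6, 11.5, 20),
                                   markers = c("L2", "L1", "P", "R1",
                                               "R2"))))
  mem <- projected_stub(c(10, 10.4), c(0.5, 0.5), c("S1", "S2"))
  fit <- fit_qtl_mixture(mem$consensus_peak, mem$sigma^2, K = 1)
  built <- build_metaqtls(fit, mem, "1A", cmap)
  # component CI is roughly [9.5, 10.9]: P (9.6) lies inside it
  expect_equal(built$regions$flank_lo, "L1")
  expect_equal(built$regions$flank_hi, "R1")
})

test_that("meta_qtl object methods expose the fit coherently", {
  sc <- synthetic_scenario(truth_config(missing_peak = 0, missing_lod = 0,
                                        missing_ci = 0), seed = 5)
  res <- meta_pipeline(sc$catalog, sc$maps, seed = 5)
  fit <- res$fit
  expect_s3_class(fit, "meta_qtl")
  expect_identical(coef(fit), fit$regions)
  expect_output(print(fit), "Meta-QTL analysis")
  s <- summary(fit)
  expect_s3_class(s, "summary.meta_qtl")
  expect_output(print(s), "fold reduction")
  expect_true(all(fit$regions$ci_lo <= fit$regions$position))
  expect_true(all(fit$regions$position <= fit$regions$ci_hi))
  expect_true(all(fit$regions$n_qtls >= 2))
  # class rule: MQTL iff >= 2 studies
  expect_equal(fit$regions$class == "MQTL", fit$regions$n_studies >= 2)
  # region members + singletons + non-supporting account for every QTL
  accounted <- sum(fit$regions$n_qtls) + length(fit$singletons) +
    length(fit$non_supporting)
  expect_equal(accounted, nrow(res$projected))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("region summaries compute fold reduction and bins", {
  mem <- projected_stub(c(10, 11, 30), c(10 / 3.92, 10 / 3.92, 4 / 3.92),
                        c("S1", "S2", "S3"))
  regions <- data.frame(mqtl_id = "MQTL1A.1", chr = "1A", position = 10.5,
                        ci_lo = 8.5, ci_hi = 12.5, ci_width = 4,
                        flank_lo = NA, flank_hi = NA, n_qtls = 2L,
                        n_studies = 2L, avg_lod = 4, avg_pve = 10,
                        class = "MQTL", stringsAsFactors = FALSE)
  s <- summarize_regions(regions, mem)
  expect_equal(s$fold_reduction, mean(c(10, 10, 4)) / 4)  # = 2.0
  expect_equal(unname(s$member_bins), c(1, 0, 0))
  s0 <- summarize_regions(regions[0, ], mem)
  expect_true(is.na(s0$fold_reduction))
  expect_equal(s0$n_regions, 0)
})
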