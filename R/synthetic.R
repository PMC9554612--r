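# Synthetic multi-study QTL data with known ground truth.
#
# The generator emulates a multi-study QTL compendium: a handful of true
# trait loci per chromosome, a master marker grid with a monotone cM-to-bp
# mapping (with a centromeric plateau imitating recombination deserts),
# per-study linkage maps (marker subsets, mildly rescaled), per-study QTL
# detection with positional noise and population-specific CI widths, and
# the downstream validation layers (GWAS MTAs, gene models, expression,
# known genes). Every stage is a pure function of (config, seed).

#' Configuration of the synthetic truth
#'
#' Defaults are desk-scale study conditions: 3 chromosomes of 300 cM /
#' 600 Mb, 3 true loci each, 10 studies detecting each locus with
#' probability 0.8 and 3 cM peak noise, populations drawn from the
#' compendium's printed ranges (RIL 93-302, DH 95-414, NIL 120).
#'
#' @param chromosomes data.frame with `chr`, `len_cM`, `len_bp`.
#' @param n_true_loci true loci per chromosome.
#' @param n_studies number of mapping studies.
#' @param p_det per-study detection probability of each true locus.
#' @param sigma_cM peak-position noise sd (cM).
#' @param pve_range PVE range (percent) of detected QTLs.
#' @param pop_mix sampling weights for population types RIL/DH/NIL.
#' @param markers_per_chr master-grid markers per chromosome.
#' @param map_subsample fraction of master markers kept per study map.
#' @param scale_jitter_sd sd of the per-study log map-scale factor.
#' @param min_locus_gap_cM minimum separation of true loci; default
#'   `4 * sigma_cM`.
#' @param missing_peak,missing_lod,missing_ci fractions of generated QTL
#'   records with the corresponding field blanked (exercises completion).
#' @param plateau_frac_cM,plateau_frac_bp centromeric plateau: fraction of
#'   the genetic length that covers `plateau_frac_bp` of the physical
#'   length.
#' @param mta_per_locus,mta_jitter_bp,mta_decoys_per_chr GWAS layer.
#' @param genes_per_locus,background_genes_per_chr gene-annotation layer.
#' @param frac_expressed fraction of genes expressed (> 2 TPM) in relevant
#'   tissues.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(
    chromosomes = data.frame(chr = c("1A", "2B", "3D"), len_cM = 300,
                             len_bp = 6e8, stringsAsFactors = FALSE),
    n_true_loci = 3, n_studies = 10, p_det = 0.8, sigma_cM = 3,
    pve_range = c(3, 15), pop_mix = c(RIL = 0.7, DH = 0.25, NIL = 0.05),
    markers_per_chr = 30, map_subsample = 0.7, scale_jitter_sd = 0.05,
    min_locus_gap_cM = NULL, missing_peak = 0.2, missing_lod = 0.3,
    missing_ci = 0.5, plateau_frac_cM = 0.1, plateau_frac_bp = 0.6,
    mta_per_locus = 2, mta_jitter_bp = 1e6, mta_decoys_per_chr = 5,
    genes_per_locus = 5, background_genes_per_chr = 10,
    frac_expressed = 0.6) {
  cfg <- as.list(environment())
  if (is.null(cfg$min_locus_gap_cM)) cfg$min_locus_gap_cM <- 4 * sigma_cM
  stopifnot(p_det >= 0, p_det <= 1, all(chromosomes$len_cM > 0),
            all(chromosomes$len_bp > 0), frac_expressed >= 0,
            frac_expressed <= 1)
  class(cfg) <- "truth_config"
  cfg
}

#' Read a scenario configuration from YAML
#' @param path YAML file whose keys match [truth_config()] arguments;
#'   `chromosomes` is a list of records.
#' @return a `truth_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$chromosomes)) {
    y$chromosomes <- do.call(rbind, lapply(y$chromosomes, as.data.frame))
  }
  if (!is.null(y$pop_mix)) y$pop_mix <- unlist(y$pop_mix)
  if (!is.null(y$pve_range)) y$pve_range <- unlist(y$pve_range)
  do.call(truth_config, y)
}

# Monotone piecewise-linear genetic-to-physical mapping with a centromeric
# plateau: a small slice of cM in the middle of the chromosome spans a
# large slice of bp, producing realistic huge physical footprints for
# mid-chromosome intervals.
cm_to_bp <- function(cM, len_cM, len_bp, frac_cM = 0.1, frac_bp = 0.6) {
  kx <- c(0, (0.5 - frac_cM / 2) * len_cM, (0.5 + frac_cM / 2) * len_cM,
          len_cM)
  ky <- c(1, (0.5 - frac_bp / 2) * len_bp, (0.5 + frac_bp / 2) * len_bp,
          len_bp)
  round(stats::approx(kx, ky, xout = pmin(pmax(cM, 0), len_cM))$y)
}

#' Generate the ground truth
#'
#' True locus positions are drawn uniformly per chromosome with minimum
#' separation `min_locus_gap_cM` (rejection sampling), deterministically
#' under `seed`.
#'
#' @param config a [truth_config()].
#' @param seed integer seed.
#' @return list of class `qtl_truth`: `loci` data.frame (`chr`, `cM`,
#'   `bp`), plus the config.
#' @export
generate_truth <- function(config, seed = 1) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(derive_seed(seed, 101))
  loci <- list()
  for (i in seq_len(nrow(config$chromosomes))) {
    ch <- config$chromosomes[i, ]
    n <- config$n_true_loci
    if (n == 0) next
    gap <- config$min_locus_gap_cM
    if ((n - 1) * gap > 0.9 * ch$len_cM) {
      stop_metaqtl("metaqtl_config_error",
                   "cannot place %d loci %g cM apart on a %g cM chromosome",
                   n, gap, ch$len_cM)
    }
    for (try in 1:1000) {
      pos <- sort(stats::runif(n, 0.05 * ch$len_cM, 0.95 * ch$len_cM))
      if (n == 1 || min(diff(pos)) >= gap) break
      if (try == 1000) {
        stop_metaqtl("metaqtl_config_error",
                     "rejection sampling failed to separate loci")
      }
    }
    loci[[ch$chr]] <- data.frame(
      chr = ch$chr, cM = pos,
      bp = cm_to_bp(pos, ch$len_cM, ch$len_bp, config$plateau_frac_cM,
                    config$plateau_frac_bp),
      stringsAsFactors = FALSE)
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chr = character(0), cM = numeric(0), bp = numeric(0))
  rownames(loci) <- NULL
  structure(list(loci = loci, config = config), class = "qtl_truth")
}

POP_SIZE_RANGES <- list(RIL = c(93, 302), DH = c(95, 414), NIL = c(120, 120))

#' Generate study-level data from the truth
#'
#' Builds the master marker grid and its physical-position table, one
#' subsampled and rescaled linkage map per study, and the QTL compendium:
#' each study detects each true locus with probability `p_det`; a detected
#' QTL gets a noisy peak, a PVE drawn from `pve_range`, a CI width from
#' [estimate_ci()], a LOD of `3 + Exp(mean 3)`, and the nearest study-map
#' markers as flanks. Missingness fractions blank peak/LOD/CI fields to
#' exercise [complete_catalog()].
#'
#' @param truth a `qtl_truth`.
#' @param seed integer seed.
#' @return list: `catalog` (`qtl_catalog`), `maps` (named list of
#'   [linkage_map()]s keyed by study id), `master` (the master
#'   `linkage_map`), `marker_table` (physical positions), `studies`
#'   (per-study metadata).
#' @export
generate_studies <- function(truth, seed = 1) {
  config <- truth$config
  set.seed(derive_seed(seed, 202))
  chrom <- config$chromosomes
  master_rows <- list()
  for (i in seq_len(nrow(chrom))) {
    ch <- chrom[i, ]
    pos <- seq(0, ch$len_cM, length.out = config$markers_per_chr)
    master_rows[[i]] <- data.frame(
      chr = ch$chr,
      marker = sprintf("M%s_%02d", ch$chr, seq_along(pos)),
      position_cM = pos, stringsAsFactors = FALSE)
  }
  master_df <- do.call(rbind, master_rows)
  master <- linkage_map("master", master_df)
  marker_table <- do.call(rbind, lapply(seq_len(nrow(chrom)), function(i) {
    ch <- chrom[i, ]
    seg <- master_df[master_df$chr == ch$chr, ]
    data.frame(marker = seg$marker, chr = ch$chr,
               bp = cm_to_bp(seg$position_cM, ch$len_cM, ch$len_bp,
                             config$plateau_frac_cM, config$plateau_frac_bp),
               stringsAsFactors = FALSE)
  }))
  studies <- data.frame(
    study_id = sprintf("S%02d", seq_len(config$n_studies)),
    pop_type = sample(names(config$pop_mix), config$n_studies,
                      replace = TRUE, prob = config$pop_mix),
    stringsAsFactors = FALSE)
  studies$pop_size <- vapply(studies$pop_type, function(tp) {
    rg <- POP_SIZE_RANGES[[tp]]
    round(stats::runif(1, rg[1], rg[2]))
  }, numeric(1))
  studies$scale <- exp(stats::rnorm(config$n_studies, 0,
                                    config$scale_jitter_sd))
  maps <- list()
  qtl_rows <- list()
  for (s in seq_len(config$n_studies)) {
    sid <- studies$study_id[s]
    keep_rows <- list()
    for (i in seq_len(nrow(chrom))) {
      seg <- master_df[master_df$chr == chrom$chr[i], ]
      n_keep <- max(2, round(nrow(seg) * config$map_subsample))
      keep <- sort(unique(c(1, nrow(seg),
                            sample(nrow(seg), n_keep))))
      sseg <- seg[keep, ]
      sseg$position_cM <- sseg$position_cM * studies$scale[s]
      keep_rows[[i]] <- sseg
    }
    smap <- linkage_map(sid, do.call(rbind, keep_rows))
    maps[[sid]] <- smap
    det <- truth$loci[stats::runif(nrow(truth$loci)) < config$p_det, ,
                      drop = FALSE]
    if (!nrow(det)) next
    for (j in seq_len(nrow(det))) {
      ch <- det$chr[j]
      seg <- map_chromosome(smap, ch)
      peak <- studies$scale[s] *
        (det$cM[j] + stats::rnorm(1, 0, config$sigma_cM))
      peak <- min(max(peak, min(seg$position_cM)), max(seg$position_cM))
      below <- which(seg$position_cM <= peak)
      above <- which(seg$position_cM >= peak)
      iL <- max(below); iR <- min(above)
      if (iL == iR) {
        if (iR < nrow(seg)) iR <- iR + 1 else iL <- iL - 1
      }
      pve <- stats::runif(1, config$pve_range[1], config$pve_range[2])
      w <- estimate_ci(studies$pop_type[s], studies$pop_size[s], pve / 100)
      qtl_rows[[length(qtl_rows) + 1]] <- data.frame(
        qtl_id = sprintf("Q_%s_%s_%d", sid, ch, j), study_id = sid,
        pop_type = studies$pop_type[s], pop_size = studies$pop_size[s],
        chr = ch, flank_lo = seg$marker[iL], flank_hi = seg$marker[iR],
        peak_cM = peak, ci_lo_cM = max(0, peak - w / 2),
        ci_hi_cM = peak + w / 2,
        lod = 3 + stats::rexp(1, 1 / 3), pve_pct = pve,
        stringsAsFactors = FALSE)
    }
  }
  catalog <- do.call(rbind, qtl_rows)
  # blank fields to exercise completion (peak only when flanks resolve it)
  n <- nrow(catalog)
  blank <- function(frac) stats::runif(n) < frac
  catalog$peak_cM[blank(config$missing_peak)] <- NA_real_
  catalog$lod[blank(config$missing_lod)] <- NA_real_
  ci_na <- blank(config$missing_ci)
  catalog$ci_lo_cM[ci_na] <- NA_real_
  catalog$ci_hi_cM[ci_na] <- NA_real_
  list(catalog = as_qtl_catalog(catalog), maps = maps, master = master,
       marker_table = as_marker_table(marker_table), studies = studies)
}

#' Generate GWAS, gene-annotation and expression layers
#'
#' MTAs are placed around true-locus physical positions (plus uniform
#' decoys); genes are tiled with a subset inside the true-locus windows;
#' TPM values are drawn from lognormal tails so that `frac_expressed` of
#' genes exceed 2 TPM in relevant tissues; one known trait gene is planted
#' at the first true locus of each chromosome.
#'
#' @param truth a `qtl_truth`.
#' @param seed integer seed.
#' @return list: `mtas`, `genes`, `expression` (gene x sample TPM matrix),
#'   `tissues` (sample -> tissue tags), `known_genes`.
#' @export
generate_validation_layers <- function(truth, seed = 1) {
  config <- truth$config
  set.seed(derive_seed(seed, 303))
  chrom <- config$chromosomes
  loci <- truth$loci
  mta_rows <- list(); gene_rows <- list(); known_rows <- list()
  for (j in seq_len(nrow(loci))) {
    lb <- chrom$len_bp[match(loci$chr[j], chrom$chr)]
    for (k in seq_len(config$mta_per_locus)) {
      bp <- min(max(1, round(loci$bp[j] +
                               stats::runif(1, -config$mta_jitter_bp,
                                            config$mta_jitter_bp))), lb)
      mta_rows[[length(mta_rows) + 1]] <- data.frame(
        snp_id = sprintf("SNP_%s_%d_%d", loci$chr[j], j, k),
        chr = loci$chr[j], bp = bp, study_id = "GWAS_SYN", trait = "GPC",
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$genes_per_locus)) {
      start <- max(1, round(loci$bp[j] + stats::runif(1, -9e5, 9e5)))
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = sprintf("G_%s_L%d_%d", loci$chr[j], j, k),
        chr = loci$chr[j], start_bp = start,
        end_bp = start + round(stats::runif(1, 2e3, 6e3)),
        description = "synthetic locus-linked gene",
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(chrom))) {
    ch <- chrom[i, ]
    for (k in seq_len(config$mta_decoys_per_chr)) {
      mta_rows[[length(mta_rows) + 1]] <- data.frame(
        snp_id = sprintf("SNP_%s_decoy_%d", ch$chr, k), chr = ch$chr,
        bp = round(stats::runif(1, 1, ch$len_bp)), study_id = "GWAS_SYN",
        trait = "GPC", stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$background_genes_per_chr)) {
      start <- round(stats::runif(1, 1, ch$len_bp - 1e4))
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = sprintf("G_%s_bg_%d", ch$chr, k), chr = ch$chr,
        start_bp = start, end_bp = start + round(stats::runif(1, 2e3, 6e3)),
        description = "synthetic background gene",
        stringsAsFactors = FALSE)
    }
    first <- loci[loci$chr == ch$chr, ]
    if (nrow(first)) {
      known_rows[[length(known_rows) + 1]] <- data.frame(
        gene_id = sprintf("KNOWN_%s", ch$chr), chr = ch$chr,
        start_bp = max(1, first$bp[1] - 5e4), end_bp = first$bp[1] + 5e4,
        description = "synthetic known trait gene",
        stringsAsFactors = FALSE)
    }
  }
  genes <- as_gene_models(do.call(rbind, gene_rows))
  tissues <- c(grain_1 = "grain", grain_2 = "grain", spike_1 = "spike",
               flagleaf_1 = "flag_leaf_senescence", root_1 = "root")
  n_genes <- nrow(genes)
  expressed <- stats::runif(n_genes) < config$frac_expressed
  expr <- matrix(0, n_genes, length(tissues),
                 dimnames = list(genes$gene_id, names(tissues)))
  for (s in seq_along(tissues)) {
    relevant <- tissues[s] %in% c("grain", "spike", "flag_leaf_senescence")
    z <- abs(stats::rnorm(n_genes))
    expr[, s] <- if (relevant) {
      ifelse(expressed, 2 * exp(z), 2 * exp(-z))
    } else {
      stats::rlnorm(n_genes, 0, 1)
    }
  }
  list(mtas = do.call(rbind, mta_rows), genes = genes, expression = expr,
       tissues = tissues,
       known_genes = do.call(rbind, known_rows))
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper chaining [generate_truth()], [generate_studies()]
#' and [generate_validation_layers()].
#'
#' @param config a [truth_config()].
#' @param seed integer seed.
#' @return list with `truth`, plus everything the two study/validation
#'   generators return.
#' @export
synthetic_scenario <- function(config = truth_config(), seed = 1) {
  truth <- generate_truth(config, seed)
  st <- generate_studies(truth, seed)
  val <- generate_validation_layers(truth, seed)
  c(list(truth = truth), st, val)
}

#' Run the full meta-QTL pipeline on compendium inputs
#'
#' Completion, consensus-map merge, projection and meta-analysis in one
#' call.
#'
#' @param catalog a `qtl_catalog`.
#' @param maps named list of study [linkage_map()]s.
#' @param Kmax,n_restarts,seed passed to [meta_qtl()].
#' @param ratio_bounds passed to [project_catalog()].
#' @return list: `catalog` (completed), `consensus`, `projected`, `report`
#'   (projection report), `fit` (the `meta_qtl` object).
#' @export
meta_pipeline <- function(catalog, maps, Kmax = 10, n_restarts = 5,
                          seed = 1, ratio_bounds = c(0.1, 10)) {
  completed <- complete_catalog(catalog, maps)
  cmap <- merge_maps(maps)
  proj <- project_catalog(completed, maps, cmap, ratio_bounds)
  fit <- meta_qtl(proj$projected, cmap, Kmax = Kmax,
                  n_restarts = n_restarts, seed = seed)
  list(catalog = completed, consensus = cmap, projected = proj$projected,
       report = proj$report, fit = fit)
}

#' Express true locus positions on the consensus scale
#'
#' The consensus map is built from rescaled study maps, so truth stated on
#' the master-map scale must be interpolated through shared markers before
#' comparing with fitted meta-QTL positions.
#'
#' @param truth a `qtl_truth`.
#' @param master the master `linkage_map` from [generate_studies()].
#' @param cmap the consensus map the pipeline produced.
#' @return `truth$loci` with a `consensus_cM` column added.
#' @export
project_truth <- function(truth, master, cmap) {
  loci <- truth$loci
  loci$consensus_cM <- NA_real_
  for (ch in unique(loci$chr)) {
    mseg <- map_chromosome(master, ch)
    cseg <- map_chromosome(cmap, ch)
    shared <- intersect(mseg$marker, cseg$marker)
    if (length(shared) < 2) next
    mp <- mseg$position_cM[match(shared, mseg$marker)]
    cp <- cseg$position_cM[match(shared, cseg$marker)]
    idx <- loci$chr == ch
    loci$consensus_cM[idx] <- stats::approx(mp, cp, xout = loci$cM[idx],
                                            rule = 2)$y
  }
  loci
}

#' Recovery metrics of a fitted pipeline against the truth
#'
#' @param fit a `meta_qtl` object.
#' @param truth_consensus output of [project_truth()].
#' @return list: `k_true`, `k_found` (per chromosome), `k_correct`
#'   fraction, `rmse_cM` (over true loci matched to their nearest region).
#' @export
recovery_metrics <- function(fit, truth_consensus) {
  chrs <- unique(truth_consensus$chr)
  k_true <- vapply(chrs, function(ch)
    sum(truth_consensus$chr == ch), integer(1))
  k_found <- vapply(chrs, function(ch)
    sum(fit$regions$chr == ch), integer(1))
  errs <- c()
  for (ch in chrs) {
    tt <- truth_consensus$consensus_cM[truth_consensus$chr == ch]
    rr <- fit$regions$position[fit$regions$chr == ch]
    if (!length(rr)) next
    errs <- c(errs, vapply(tt, function(p) min(abs(p - rr)), numeric(1)))
  }
  list(k_true = k_true, k_found = k_found,
       k_correct = mean(k_found == k_true),
       rmse_cM = if (length(errs)) sqrt(mean(errs^2)) else NA_real_)
}
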