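# Independent oracles and small fixture builders used across the suite.

# Tiny linkage-map constructor: chr fixed, markers named by letters.
tiny_map <- function(id, pos, chr = "1A", markers = LETTERS[seq_along(pos)]) {
  linkage_map(id, data.frame(chr = chr, marker = markers,
                             position_cM = pos))
}

# One-row catalog builder with sensible defaults.
tiny_qtl <- function(qtl_id = "q1", study_id = "s1", pop_type = "RIL",
                     pop_size = 150, chr = "1A", flank_lo = "A",
                     flank_hi = "B", peak_cM = 5, ci_lo_cM = 2,
                     ci_hi_cM = 8, lod = 4, pve_pct = 10) {
  as_qtl_catalog(data.frame(qtl_id = qtl_id, study_id = study_id,
                            pop_type = pop_type, pop_size = pop_size,
                            chr = chr, flank_lo = flank_lo,
                            flank_hi = flank_hi, peak_cM = peak_cM,
                            ci_lo_cM = ci_lo_cM, ci_hi_cM = ci_hi_cM,
                            lod = lod, pve_pct = pve_pct,
                            stringsAsFactors = FALSE))
}

# Brute-force oracle for the consensus-merge objective: exhaustive grid
# search over candidate positions for every marker (first marker fixed at
# 0), honouring the retained order constraints. Only viable for <= 6
# markers; returns the minimal achievable L1 objective.
merge_oracle_objective <- function(maps, chr, grid_step = 0.4) {
  edges <- metaqtl:::chromosome_edges(maps, chr)
  markers <- unique(c(edges$from, edges$to))
  spans <- vapply(maps, function(m) {
    seg <- m[m$chr == chr, ]
    if (nrow(seg)) diff(range(seg$position_cM)) else 0
  }, numeric(1))
  grid <- seq(0, 1.5 * max(spans), by = grid_step)
  first <- markers[1]
  others <- markers[-1]
  combos <- do.call(expand.grid, rep(list(grid), length(others)))
  best <- Inf
  pair_keys <- unique(paste(edges$from, edges$to))
  for (i in seq_len(nrow(combos))) {
    pos <- c(0, as.numeric(combos[i, ]))
    names(pos) <- c(first, others)
    gaps <- pos[edges$to] - pos[edges$from]
    if (any(gaps < 0)) next                     # violates retained order
    obj <- sum(edges$weight * abs(gaps - edges$d))
    if (obj < best) best <- obj
  }
  best
}

# Grid-search maximum-likelihood oracle for the 1-D mixture with known
# variances, K = 1 or 2. Exhaustive over component means (and weight for
# K = 2); independent of the EM implementation.
mixture_oracle_loglik <- function(x, s2, K, mu_step = 0.25,
                                  pi_grid = seq(0.1, 0.9, by = 0.1)) {
  mus <- seq(min(x) - 0.5, max(x) + 0.5, by = mu_step)
  sdv <- sqrt(s2)
  # density of each observation at each candidate mean (n x |mus|)
  dens <- vapply(mus, function(m) stats::dnorm(x, m, sdv),
                 numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  if (K == 1) {
    return(max(colSums(log(dens))))
  }
  best <- -Inf
  for (i in seq_along(mus)) for (j in seq.int(i, length(mus))) {
    for (p in pi_grid) {
      ll <- sum(log(p * dens[, i] + (1 - p) * dens[, j]))
      if (ll > best) best <- ll
    }
  }
  best
}

# All-pairs inclusive interval-overlap check (oracle for the
# GenomicRanges-backed window/co-localization scans).
overlap_oracle <- function(a_chr, a_lo, a_hi, b_chr, b_lo, b_hi) {
  out <- matrix(FALSE, length(a_chr), length(b_chr))
  for (i in seq_along(a_chr)) for (j in seq_along(b_chr)) {
    out[i, j] <- a_chr[i] == b_chr[j] && a_lo[i] <= b_hi[j] &&
      b_lo[j] <= a_hi[i]
  }
  out
}

# Random catalog generator for property tests (valid, completed records).
random_catalog <- function(n, seed) {
  set.seed(seed)
  chrs <- sample(c("1A", "2B", "3D", "5B"), n, replace = TRUE)
  peak <- runif(n, 0, 100)
  w <- runif(n, 0.5, 30)
  as_qtl_catalog(data.frame(
    qtl_id = sprintf("q%03d", seq_len(n)), study_id = "s1",
    pop_type = sample(c("RIL", "DH"), n, replace = TRUE),
    pop_size = sample(90:400, n, replace = TRUE), chr = chrs,
    flank_lo = "A", flank_hi = "B", peak_cM = peak,
    ci_lo_cM = pmax(0, peak - w / 2), ci_hi_cM = peak + w / 2,
    lod = runif(n, 2.5, 20), pve_pct = runif(n, 1, 30),
    stringsAsFactors = FALSE))
}
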