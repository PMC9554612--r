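# Consensus-map construction.
#
# Per chromosome the merge solves a linear program: choose consensus
# positions y minimizing the weighted mean absolute error between consensus
# adjacent-marker distances and the distances observed in each component
# map, subject to y_b - y_a >= min_gap for every retained ordinal
# constraint. Conflicting marker orders are first reduced to an acyclic
# constraint set by greedy feedback-edge removal. The LP is solved as a
# constrained median (L1) regression.

# Build the directed adjacency constraint list for one chromosome.
# One row per adjacent marker pair per component map.
chromosome_edges <- function(maps, chr) {
  rows <- list()
  for (m in maps) {
    seg <- map_chromosome(m, chr)
    if (nrow(seg) < 2) next
    n_pairs <- nrow(seg) - 1
    for (k in seq_len(n_pairs)) {
      rows[[length(rows) + 1]] <- data.frame(
        from = seg$marker[k], to = seg$marker[k + 1],
        d = seg$position_cM[k + 1] - seg$position_cM[k],
        map_id = seg$map_id[1], weight = 1 / n_pairs,
        n_map_markers = nrow(seg), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(from = character(0), to = character(0), d = numeric(0),
                      map_id = character(0), weight = numeric(0),
                      n_map_markers = integer(0)))
  }
  do.call(rbind, rows)
}

# Find one directed cycle (as a vector of "from>to" pair keys) or NULL.
find_cycle <- function(pairs) {
  adj <- split(pairs$to, pairs$from)
  color <- new.env(parent = emptyenv())
  stack_path <- character(0)
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return()
    assign(v, 1L, envir = color)                       # grey: on stack
    stack_path <<- c(stack_path, v)
    for (w in adj[[v]] %||% character(0)) {
      st <- if (exists(w, envir = color)) get(w, envir = color) else 0L
      if (st == 1L) {
        i <- match(w, stack_path)
        verts <- c(stack_path[i:length(stack_path)], w)
        cycle <<- paste(verts[-length(verts)], verts[-1], sep = ">")
        return()
      } else if (st == 0L) {
        visit(w)
        if (!is.null(cycle)) return()
      }
    }
    stack_path <<- stack_path[-length(stack_path)]
    assign(v, 2L, envir = color)                       # black: done
  }
  for (v in unique(pairs$from)) {
    st <- if (exists(v, envir = color)) get(v, envir = color) else 0L
    if (st == 0L) visit(v)
    if (!is.null(cycle)) break
  }
  cycle
}

#' Resolve marker-order conflicts among linkage maps
#'
#' Component maps can disagree on marker order; the union of their ordinal
#' constraints then contains directed cycles. A (greedy, approximate)
#' minimum set of constraints is removed: from any remaining cycle, delete
#' the constraint supported by the fewest component maps, breaking ties
#' first by the total marker count of the supporting maps (fewer first),
#' then lexicographically.
#'
#' @param maps list of [linkage_map()] objects.
#' @param chr chromosome label to analyse.
#' @return list with `retained` and `removed` data.frames of directed
#'   constraints (`from`, `to`, `support` = number of supporting maps).
#' @export
resolve_order_conflicts <- function(maps, chr) {
  edges <- chromosome_edges(maps, chr)
  key <- paste(edges$from, edges$to, sep = ">")
  agg <- function(keys) {
    u <- unique(keys)
    data.frame(
      key = u,
      from = edges$from[match(u, key)],
      to = edges$to[match(u, key)],
      support = vapply(u, function(k) length(unique(edges$map_id[key == k])),
                       integer(1)),
      support_markers = vapply(u, function(k)
        sum(edges$n_map_markers[key == k][!duplicated(edges$map_id[key == k])]),
        numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  pairs <- agg(key)
  removed_keys <- character(0)
  repeat {
    live <- pairs[!(pairs$key %in% removed_keys), ]
    cyc <- find_cycle(live)
    if (is.null(cyc)) break
    cand <- live[live$key %in% cyc, ]
    ord <- order(cand$support, cand$support_markers, cand$key)
    removed_keys <- c(removed_keys, cand$key[ord[1]])
  }
  retained <- pairs[!(pairs$key %in% removed_keys),
                    c("from", "to", "support")]
  removed <- pairs[pairs$key %in% removed_keys, c("from", "to", "support")]
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed,
       edges = edges[!(key %in% removed_keys), , drop = FALSE])
}

# Solve the consensus LP for one connected component of the constraint
# graph. Returns named positions (reference marker at 0).
solve_component_lp <- function(markers, edges, pairs, min_gap, mean_pos) {
  if (length(markers) == 1) {
    return(stats::setNames(0, markers))
  }
  ref <- markers[order(mean_pos[markers], markers)][1]
  free <- setdiff(markers, ref)
  col_of <- stats::setNames(seq_along(free), free)
  row_vec <- function(from, to) {
    v <- numeric(length(free))
    if (to != ref) v[col_of[[to]]] <- 1
    if (from != ref) v[col_of[[from]]] <- -1
    v
  }
  as_rows <- function(n, fn) {
    v <- vapply(seq_len(n), fn, numeric(length(free)))
    if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
  }
  # primary rows: one per map adjacency, weighted 1/n_pairs(map)
  Xp <- as_rows(nrow(edges),
                function(i) row_vec(edges$from[i], edges$to[i]))
  dp <- edges$d
  wp <- edges$weight
  # secondary (tie-break) rows: per unique pair, target = mean map distance
  ekey <- paste(edges$from, edges$to, sep = ">")
  pkey <- paste(pairs$from, pairs$to, sep = ">")
  dbar <- vapply(pkey, function(k) mean(edges$d[ekey == k]), numeric(1))
  Xs <- as_rows(nrow(pairs),
                function(i) row_vec(pairs$from[i], pairs$to[i]))
  ws <- rep(1e-3 * min(wp), nrow(pairs))
  X <- rbind(Xp * wp, Xs * ws)
  y <- c(dp * wp, dbar * ws)
  R <- Xs
  r <- rep(min_gap, nrow(pairs))
  fit <- quantreg::rq.fit.fnc(X, y, R = R, r = r, tau = 0.5)
  pos <- stats::setNames(numeric(length(markers)), markers)
  pos[free] <- fit$coefficients
  pos
}

# Undirected connected components over the constraint pairs.
constraint_components <- function(markers, pairs) {
  comp <- stats::setNames(seq_along(markers), markers)
  for (i in seq_len(nrow(pairs))) {
    a <- comp[[pairs$from[i]]]; b <- comp[[pairs$to[i]]]
    if (a != b) comp[comp == b] <- a
  }
  split(names(comp), comp)
}

#' Merge linkage maps into a consensus map
#'
#' Per chromosome, minimizes the weighted mean absolute error between
#' consensus and component adjacent-marker distances subject to every
#' retained ordinal constraint (`y_b - y_a >= min_gap`), after greedy
#' removal of conflicting constraints ([resolve_order_conflicts()]).
#' Among equally optimal configurations, positions closest (in L1) to the
#' per-pair mean component distances are preferred, so flat optima resolve
#' to the midpoint of the component distances. Markers carrying no
#' constraint are placed by interpolation on their source maps. The first
#' marker of each chromosome ends at 0 cM.
#'
#' @param maps list of [linkage_map()] objects.
#' @param min_gap minimum consensus distance (cM) enforced for each ordered
#'   pair; default `1e-6` makes strict order LP-representable.
#' @return a `consensus_map` data.frame (`chr`, `marker`, `position_cM`,
#'   `n_source_maps`) with attributes `removed_constraints` (data.frame) and
#'   `objective` (named per-chromosome L1 objective values).
#' @export
merge_maps <- function(maps, min_gap = 1e-6) {
  if (length(maps) == 0) {
    stop_metaqtl("metaqtl_input_error", "no maps supplied")
  }
  chrs <- sort(unique(unlist(lapply(maps, function(m) unique(m$chr)))))
  removed_all <- list()
  objective <- numeric(0)
  out <- list()
  for (ch in chrs) {
    segs <- lapply(maps, map_chromosome, chr = ch)
    segs <- segs[vapply(segs, nrow, integer(1)) > 0]
    markers <- unique(unlist(lapply(segs, function(s) s$marker)))
    src_pos <- lapply(segs, function(s)
      stats::setNames(s$position_cM, s$marker))
    mean_pos <- vapply(markers, function(mk)
      mean(unlist(lapply(src_pos, function(p) p[mk])), na.rm = TRUE),
      numeric(1))
    n_src <- vapply(markers, function(mk)
      sum(vapply(src_pos, function(p) mk %in% names(p), logical(1))),
      integer(1))
    if (length(markers) < 2) {
      if (length(markers) == 1) {
        warning(sprintf("chromosome %s has a single marker; passed through",
                        ch))
        out[[ch]] <- data.frame(chr = ch, marker = markers, position_cM = 0,
                                n_source_maps = n_src,
                                stringsAsFactors = FALSE)
      }
      next
    }
    res <- resolve_order_conflicts(maps, ch)
    removed_all[[ch]] <- res$removed
    pairs <- res$retained
    edges <- res$edges
    pos <- stats::setNames(rep(NA_real_, length(markers)), markers)
    if (nrow(pairs)) {
      comps <- constraint_components(
        unique(c(pairs$from, pairs$to)), pairs)
      for (cm in comps) {
        e_sub <- edges[edges$from %in% cm & edges$to %in% cm, , drop = FALSE]
        p_sub <- pairs[pairs$from %in% cm & pairs$to %in% cm, , drop = FALSE]
        p <- solve_component_lp(cm, e_sub, p_sub, min_gap, mean_pos)
        # anchor the component at its markers' mean source position
        p <- p - mean(p) + mean(mean_pos[cm])
        pos[cm] <- p
      }
    }
    # unconstrained markers: interpolate between placed source-map neighbours
    loose <- names(pos)[is.na(pos)]
    for (mk in loose) {
      est <- c()
      for (p_src in src_pos) {
        if (!(mk %in% names(p_src))) next
        placed <- names(p_src)[!is.na(pos[names(p_src)]) &
                                 names(p_src) != mk]
        if (!length(placed)) next
        x0 <- p_src[[mk]]
        below <- placed[p_src[placed] <= x0]
        above <- placed[p_src[placed] > x0]
        if (length(below) && length(above)) {
          bL <- below[which.max(p_src[below])]
          bR <- above[which.min(p_src[above])]
          f <- (x0 - p_src[[bL]]) / (p_src[[bR]] - p_src[[bL]])
          est <- c(est, pos[[bL]] + f * (pos[[bR]] - pos[[bL]]))
        } else if (length(below)) {
          bL <- below[which.max(p_src[below])]
          est <- c(est, pos[[bL]] + (x0 - p_src[[bL]]))
        } else {
          bR <- above[which.min(p_src[above])]
          est <- c(est, pos[[bR]] - (p_src[[bR]] - x0))
        }
      }
      pos[[mk]] <- if (length(est)) mean(est) else mean_pos[[mk]]
    }
    pos <- pos - min(pos)
    obj <- sum(edges$weight *
                 abs((pos[edges$to] - pos[edges$from]) - edges$d))
    objective[ch] <- obj
    df <- data.frame(chr = ch, marker = names(pos),
                     position_cM = unname(pos),
                     n_source_maps = unname(n_src[names(pos)]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$position_cM, df$marker), ]
    out[[ch]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- cbind(map_id = "consensus", res)
  structure(res, class = c("consensus_map", "linkage_map", "data.frame"),
            removed_constraints = do.call(rbind, removed_all),
            objective = objective)
}

# L1 merge objective of an arbitrary candidate position assignment;
# used for diagnostics and oracle comparisons.
merge_objective <- function(maps, chr, positions) {
  edges <- chromosome_edges(maps, chr)
  sum(edges$weight *
        abs((positions[edges$to] - positions[edges$from]) - edges$d))
}
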