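# Consensus-map merging: LP solution quality, conflict resolution and
# map statistics.

test_that("merging a single map returns it, rebased to zero", {
  m <- tiny_map("m1", c(3, 13, 20))
  cm <- merge_maps(list(m))
  expect_equal(cm$marker, c("A", "B", "C"))
  expect_equal(cm$position_cM, c(0, 10, 17), tolerance = 1e-4)
  # two identical maps agree with either one
  cm2 <- merge_maps(list(m, tiny_map("m2", c(3, 13, 20))))
  expect_equal(cm2$position_cM, c(0, 10, 17), tolerance = 1e-4)
})

test_that("a flat L1 optimum resolves to the midpoint of component distances", {
  m1 <- tiny_map("m1", c(0, 10))
  m2 <- tiny_map("m2", c(0, 20))
  cm <- merge_maps(list(m1, m2))
  # any B in [10, 20] minimizes |B-10|+|B-20|; tie-break picks 15
  expect_equal(cm$position_cM[cm$marker == "B"], 15, tolerance = 1e-3)
})

test_that("order conflicts are removed by majority support", {
  m1 <- tiny_map("m1", c(0, 10))                      # A < B
  m2 <- tiny_map("m2", c(0, 20))                      # A < B
  m3 <- tiny_map("m3", c(0, 5), markers = c("B", "A"))  # B < A
  rc <- resolve_order_conflicts(list(m1, m2, m3), "1A")
  expect_equal(nrow(rc$removed), 1)
  expect_equal(rc$removed$from, "B")
  expect_equal(rc$removed$to, "A")
  expect_equal(rc$removed$support, 1)
})

test_that("a 3-cycle with equal support loses exactly one edge and becomes acyclic", {
  # A<B (m1), B<C (m2), C<A (m3): every edge supported once
  m1 <- tiny_map("m1", c(0, 10), markers = c("A", "B"))
  m2 <- tiny_map("m2", c(0, 10), markers = c("B", "C"))
  m3 <- tiny_map("m3", c(0, 10), markers = c("C", "A"))
  rc <- resolve_order_conflicts(list(m1, m2, m3), "1A")
  expect_equal(nrow(rc$removed), 1)
  expect_equal(nrow(rc$retained), 2)
  # exhaustive: removing any single edge of a 3-cycle breaks it, so the
  # result must be acyclic whichever edge greedy picked
  expect_null(metaqtl:::find_cycle(rc$retained))
  # no cycles -> nothing removed
  rc2 <- resolve_order_conflicts(list(m1, m2), "1A")
  expect_equal(nrow(rc2$removed), 0)
})

test_that("every retained order constraint holds in the merged map", {
  for (seed in 1:5) {
    set.seed(seed)
    true <- sort(runif(8, 0, 100))
    maps <- lapply(1:4, function(j) {
      idx <- sort(sample(8, 6))
      tiny_map(paste0("m", j), true[idx] * exp(rnorm(1, 0, 0.1)),
               markers = LETTERS[idx])
    })
    cm <- merge_maps(maps)
    rc <- resolve_order_conflicts(maps, "1A")
    pos <- setNames(cm$position_cM, cm$marker)
    gaps <- pos[rc$retained$to] - pos[rc$retained$from]
    expect_true(all(gaps >= 1e-6 - 1e-8))
  }
})

test_that("merging the consensus with itself is a fixed point", {
  maps <- list(tiny_map("m1", c(0, 8, 25, 40)),
               tiny_map("m2", c(0, 12, 22, 39)))
  cm <- merge_maps(maps)
  again <- merge_maps(list(linkage_map("c", as.data.frame(cm))))
  expect_equal(again$position_cM, cm$position_cM, tolerance = 1e-4)
  expect_equal(again$marker, cm$marker)
})

test_that("solver objective is no worse than the first map's feasible point", {
  for (seed in 1:5) {
    set.seed(seed)
    true <- sort(runif(6, 0, 80))
    maps <- lapply(1:3, function(j)
      tiny_map(paste0("m", j), true * exp(rnorm(1, 0, 0.08))))
    cm <- merge_maps(maps)
    pos <- setNames(cm$position_cM, cm$marker)
    obj_solver <- metaqtl:::merge_objective(maps, "1A", pos)
    naive <- setNames(maps[[1]]$position_cM, maps[[1]]$marker)
    obj_naive <- metaqtl:::merge_objective(maps, "1A", naive)
    expect_lte(obj_solver, obj_naive + 1e-6)
  }
})

test_that("LP solution matches brute-force search on small instances", {
  for (seed in 1:3) {
    set.seed(seed)
    true <- sort(runif(4, 0, 12))
    maps <- lapply(1:3, function(j) {
      idx <- sort(sample(4, 3))
      tiny_map(paste0("m", j), true[idx] * exp(rnorm(1, 0, 0.15)),
               markers = LETTERS[idx])
    })
    cm <- merge_maps(maps)
    pos <- setNames(cm$position_cM, cm$marker)
    obj_solver <- metaqtl:::merge_objective(maps, "1A", pos)
    obj_oracle <- merge_oracle_objective(maps, "1A", grid_step = 0.2)
    # solver must be at least as good as the grid optimum (to grid error)
    expect_lte(obj_solver, obj_oracle + 1e-3)
  }
})

test_that("map statistics report length, density and degenerate chromosomes", {
  m <- linkage_map("m", data.frame(
    chr = c(rep("1A", 11), "2B"),
    marker = c(sprintf("a%02d", 1:11), "z"),
    position_cM = c(seq(0, 100, by = 10), 5)))
  st <- map_stats(m)
  a <- st$per_chromosome[st$per_chromosome$chr == "1A", ]
  expect_equal(a$length_cM, 100)
  expect_equal(a$density, 11 / 100)
  b <- st$per_chromosome[st$per_chromosome$chr == "2B", ]
  expect_equal(b$length_cM, 0)
  expect_true(is.na(b$density))
  expect_equal(st$total$n_markers, 12)
  expect_equal(st$total$length_cM, 100)
})

test_that("degenerate merges error or warn as appropriate", {
  expect_error(merge_maps(list()), class = "metaqtl_input_error")
  single <- tiny_map("m1", 5, markers = "A")
  expect_warning(merge_maps(list(single)), "single marker")
})
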