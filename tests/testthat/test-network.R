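edge_tbl <- function(...) {
  e <- tibble::tibble(...)
  if (!"type_a" %in% names(e)) e$type_a <- "protein"
  if (!"type_b" %in% names(e)) e$type_b <- "protein"
  if (!"confidence" %in% names(e)) e$confidence <- 0.9
  e
}

test_that("interactome construction filters, deduplicates and drops non-proteins", {
  e <- edge_tbl(id_a = c("a", "b", "a", "c", "x"),
                id_b = c("b", "a", "a", "d", "y"),
                confidence = c(0.9, 0.9, 0.9, 0.4, 0.8),
                type_a = c("protein", "protein", "protein", "protein",
                           "rna"),
                type_b = "protein")
  g <- build_interactome(e, confidence_min = 0.5)
  expect_equal(igraph::ecount(g), 1)          # a-b kept once, loop dropped
  expect_false("c" %in% igraph::V(g)$name)    # low confidence
  expect_false("x" %in% igraph::V(g)$name)    # non-protein endpoint
  g2 <- build_interactome(e[1:4, ], confidence_min = NULL)
  expect_equal(igraph::ecount(g2), 2)         # no evidence filter
  expect_message(build_interactome(edge_tbl(id_a = c("a", NA),
                                            id_b = c("b", "c"))),
                 "malformed")
})

test_that("minimum set distances follow path lengths, overlap and reachability", {
  g <- build_interactome(edge_tbl(id_a = c("a", "b", "d"),
                                  id_b = c("b", "c", "e")))
  expect_equal(min_set_distance(g, "a", "c")$distance, 2)
  expect_equal(min_set_distance(g, c("a", "b"), c("b", "c"))$distance, 0)
  un <- min_set_distance(g, "a", "d")
  expect_equal(un$distance, Inf)
  expect_false(un$reachable)
  expect_warning(r <- min_set_distance(g, c("a", "zz"), "c"), "unmapped")
  expect_equal(r$distance, 2)
  expect_error(suppressWarnings(min_set_distance(g, "zz", "c")),
               "maps into")
})

test_that("set distances agree with a Floyd-Warshall oracle on random graphs", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(8:30, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(n:(3 * n), 1)
    edges <- tibble::tibble(id_a = sample(nodes, m, replace = TRUE),
                            id_b = sample(nodes, m, replace = TRUE))
    edges <- edges[edges$id_a != edges$id_b, ]
    g <- build_interactome(edges, confidence_min = NULL)
    d_oracle <- oracle_floyd(nodes, edges)
    gn <- igraph::V(g)$name
    for (q in 1:5) {
      sa <- sample(gn, sample(1:3, 1))
      sb <- sample(gn, sample(1:3, 1))
      want <- min(d_oracle[sa, sb, drop = FALSE])
      got <- min_set_distance(g, sa, sb)$distance
      expect_equal(got, want)
      rev <- suppressWarnings(min_set_distance(g, sb, sa)$distance)
      expect_equal(got, rev)  # symmetry
    }
  }
})

test_that("adding an edge never increases a finite set distance", {
  set.seed(32)
  nodes <- sprintf("n%02d", 1:15)
  edges <- tibble::tibble(id_a = sample(nodes, 20, replace = TRUE),
                          id_b = sample(nodes, 20, replace = TRUE))
  edges <- edges[edges$id_a != edges$id_b, ]
  g1 <- build_interactome(edges, confidence_min = NULL)
  new <- tibble::tibble(id_a = "n01", id_b = "n15")
  g2 <- build_interactome(rbind(edges, new), confidence_min = NULL)
  for (q in 1:10) {
    sa <- sample(igraph::V(g1)$name, 2)
    sb <- sample(igraph::V(g1)$name, 2)
    d1 <- min_set_distance(g1, sa, sb)$distance
    d2 <- min_set_distance(g2, sa, sb)$distance
    expect_lte(d2, d1)
  }
})

test_that("synergy rate peaks in the planted close-distance bins", {
  # combinations whose targets are 1-2 hops apart are planted synergistic
  combos <- sprintf("cmb%02d", 1:12)
  dist <- tibble::tibble(combination = combos,
                         distance = rep(c(1, 2, 4, 5), each = 3))
  rates <- tibble::tibble(combination = combos,
                          rate = c(rep(0.3, 6), rep(0.02, 6)))
  sr <- synergy_rate_by_distance(dist, rates)
  b <- sr$bins
  expect_equal(b$mean_rate[b$distance %in% c(1, 2)], c(0.3, 0.3))
  expect_true(all(b$mean_rate[b$distance %in% c(4, 5)] < 0.1))
  expect_true(all(c("distance_1", "distance_2", "p_value") %in%
                    names(sr$tests)))
  # empty bins are absent
  expect_false(3 %in% b$distance)
})

test_that("the shuffle null is seeded, reproducible and detects planted proximity", {
  set.seed(33)
  nodes <- sprintf("p%02d", 1:20)
  ring <- tibble::tibble(id_a = nodes, id_b = nodes[c(2:20, 1)])
  g <- build_interactome(ring, confidence_min = NULL)
  targets <- list(d1 = "p01", d2 = "p05", d3 = "p10", d4 = "p15")
  feats <- list(f1 = "p01", f2 = "p05", f3 = "p10", f4 = "p15")
  pairs <- tibble::tibble(target_id = names(targets),
                          feature_id = names(feats))
  r1 <- shuffle_null(g, targets, feats, pairs, n_perm = 20, seed = 7)
  r2 <- shuffle_null(g, targets, feats, pairs, n_perm = 20, seed = 7)
  expect_identical(r1, r2)
  # genuine pairing sits at distance 0; shuffles mostly do not
  expect_true(all(r1$genuine$distance == 0))
  expect_gt(mean(r1$genuine$distance == 0),
            mean(r1$null$distance == 0))
})
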