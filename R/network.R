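#' Build a confidence-filtered protein interactome
#'
#' Constructs an undirected protein-protein interaction graph from an
#' edge list, keeping rows whose confidence reaches the threshold and
#' whose endpoints are both proteins, then removing self-loops and
#' duplicate (unordered) edges. Rows with missing endpoints are skipped
#' and counted.
#'
#' @param edges Data frame with columns `id_a`, `id_b` and optionally
#'   `type_a`, `type_b` (rows kept only when both equal `"protein"`) and
#'   `confidence`.
#' @param confidence_min Minimum confidence (default 0.5); `NULL` applies
#'   no filter (e.g. for sources without evidence scores).
#' @return An undirected [igraph::igraph] graph with attributes
#'   `confidence_min` and `n_malformed`.
#' @export
build_interactome <- function(edges, confidence_min = 0.5) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("id_a", "id_b") %in% names(edges)))
  ok <- !is.na(edges$id_a) & !is.na(edges$id_b) &
    nzchar(edges$id_a) & nzchar(edges$id_b)
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    message("skipped ", n_malformed, " malformed edge row(s)")
  }
  edges <- edges[ok, ]
  if (all(c("type_a", "type_b") %in% names(edges))) {
    edges <- edges[edges$type_a == "protein" & edges$type_b == "protein", ]
  }
  if (!is.null(confidence_min) && "confidence" %in% names(edges)) {
    edges <- edges[!is.na(edges$confidence) &
                     edges$confidence >= confidence_min, ]
  }
  g <- igraph::graph_from_data_frame(edges[, c("id_a", "id_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "confidence_min",
                              confidence_min %||% NA_real_)
  igraph::set_graph_attr(g, "n_malformed", n_malformed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum finite distance between two node sets
#'
#' Shortest-path (unweighted, breadth-first) distances are computed for
#' every cross pair of the two sets and the smallest finite value is
#' reported, together with the contributing node pair (lexicographically
#' smallest on ties). Identifiers absent from the graph are dropped with
#' a warning; overlapping sets have distance 0.
#'
#' @param graph An interactome graph from [build_interactome()].
#' @param set_a,set_b Character vectors of node identifiers (e.g. the
#'   targets of two drugs, or targets and biomarker proteins).
#' @return One-row tibble: `distance` (nonnegative integer; `Inf` when no
#'   pair is connected), `reachable`, `node_a`, `node_b`.
#' @export
min_set_distance <- function(graph, set_a, set_b) {
  nodes <- igraph::V(graph)$name
  a <- intersect(unique(set_a), nodes)
  b <- intersect(unique(set_b), nodes)
  dropped <- setdiff(c(unique(set_a), unique(set_b)), nodes)
  if (length(dropped)) {
    warning("unmapped identifier(s) dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(a) == 0 || length(b) == 0) {
    stop("no queried node maps into the interactome")
  }
  d <- igraph::distances(graph, v = a, to = b)
  if (all(!is.finite(d))) {
    return(tibble::tibble(distance = Inf, reachable = FALSE,
                          node_a = NA_character_, node_b = NA_character_))
  }
  dmin <- min(d[is.finite(d)])
  hits <- which(d == dmin, arr.ind = TRUE)
  pairs <- data.frame(node_a = rownames(d)[hits[, 1]],
                      node_b = colnames(d)[hits[, 2]])
  pairs <- pairs[order(pairs$node_a, pairs$node_b), ]
  tibble::tibble(distance = dmin, reachable = TRUE,
                 node_a = pairs$node_a[1], node_b = pairs$node_b[1])
}

#' Synergy rate by target-target network distance
#'
#' Joins per-combination minimum target-target distances with
#' per-combination synergy rates, summarizes combination counts and mean
#' synergy rates per integer distance bin, and tests all bin pairs with
#' two-sided t-tests (bins with fewer than 2 combinations are excluded
#' from testing; unreachable combinations are excluded from the table).
#'
#' @param distances Tibble: `combination`, `distance`.
#' @param rates Tibble: `combination`, `rate` (e.g. from
#'   [synergy_rate()]).
#' @return List: `bins` (tibble `distance`, `n`, `mean_rate`) and `tests`
#'   (tibble `distance_1`, `distance_2`, `p_value`).
#' @export
synergy_rate_by_distance <- function(distances, rates) {
  m <- dplyr::inner_join(distances, rates, by = "combination")
  m <- m[is.finite(m$distance), ]
  bins <- dplyr::summarise(dplyr::group_by(m, .data$distance),
                           n = dplyr::n(),
                           mean_rate = mean(.data$rate),
                           .groups = "drop")
  testable <- bins$distance[bins$n >= 2]
  tests <- NULL
  if (length(testable) >= 2) {
    cmb <- utils::combn(sort(testable), 2)
    tests <- tibble::tibble(
      distance_1 = cmb[1, ], distance_2 = cmb[2, ],
      p_value = apply(cmb, 2, function(pr) {
        x <- m$rate[m$distance == pr[1]]
        y <- m$rate[m$distance == pr[2]]
        if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          return(if (mean(x) == mean(y)) 1 else 0)
        }
        stats::t.test(x, y)$p.value
      }))
  }
  list(bins = bins, tests = tests)
}

#' Shuffle null for target-biomarker distances
#'
#' Recomputes minimum target-biomarker distances after randomly shuffling
#' the biomarker feature assignments without replacement, simulating
#' false-positive biomarker associations. The genuine pairing is returned
#' alongside `n_perm` permuted distance sets; the generator is seeded and
#' reproducible.
#'
#' @param graph Interactome graph.
#' @param target_sets Named list: drug/combination id -> character vector
#'   of target protein ids.
#' @param feature_sets Named list: biomarker feature id -> character
#'   vector of protein ids.
#' @param pairs Tibble of genuine associations: `target_id`,
#'   `feature_id`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List: `genuine` (tibble `target_id`, `feature_id`, `distance`)
#'   and `null` (same columns plus `perm`).
#' @export
shuffle_null <- function(graph, target_sets, feature_sets, pairs,
                         n_perm = 100, seed = 1L) {
  stopifnot(n_perm >= 1)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("target_id", "feature_id") %in% names(pairs)))
  if (length(unique(pairs$feature_id)) < 2) {
    warning("fewer than 2 distinct features: permutation is degenerate")
  }
  dist_one <- function(tid, fid) {
    res <- tryCatch(
      suppressWarnings(min_set_distance(graph, target_sets[[tid]],
                                        feature_sets[[fid]])),
      error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$distance
  }
  genuine <- pairs
  genuine$distance <- mapply(dist_one, pairs$target_id, pairs$feature_id)

  set.seed(seed)
  null <- dplyr::bind_rows(lapply(seq_len(n_perm), function(p) {
    perm <- pairs
    perm$feature_id <- sample(perm$feature_id)
    perm$distance <- mapply(dist_one, perm$target_id, perm$feature_id)
    perm$perm <- p
    perm
  }))
  list(genuine = genuine, null = null)
}

#' Read an interaction edge list
#'
#' Delimited text with columns `id_a`, `id_b`, `type_a`, `type_b`,
#' `confidence` (a minimal PSI-MITAB-like contract).
#'
#' @param path Path to a tab-delimited edge list.
#' @return Tibble of edges.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
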