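# Independent oracles and small fixture builders (no package internals).

# step-up Benjamini-Hochberg, written out from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# all-pairs shortest paths by Floyd-Warshall on an edge list
oracle_floyd <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$id_a[i], nodes)
    b <- match(edges$id_b[i], nodes)
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# straight-line re-evaluation of the plate QC rules
oracle_qc_pass <- function(wells, cv_max = 0.18, z_min = 0.3,
                           ratio_min = 4) {
  neg <- wells$intensity[wells$well_role == "dmso"]
  blank <- wells$intensity[wells$well_role == "blank"]
  cv <- sd(neg) / mean(neg)
  zf <- function(n, p) 1 - 3 * (sd(p) + sd(n)) / abs(mean(p) - mean(n))
  zs <- c()
  for (cls in c("pos1", "pos2")) {
    pc <- wells$intensity[wells$well_role == cls]
    if (mean(neg) / mean(pc) >= ratio_min) zs <- c(zs, zf(neg, pc))
  }
  if (length(zs) == 0) zs <- zf(neg, blank)
  cv <= cv_max && all(zs >= z_min)
}

# a randomized synthetic control plate spanning pass and fail regimes
random_qc_plate <- function(seed) {
  set.seed(seed)
  B <- 500; NC <- 50000
  cv_true <- runif(1, 0.02, 0.35)
  pc1_v <- runif(1, 0.02, 0.6)   # sometimes ratio < 4
  pc2_v <- runif(1, 0.02, 0.6)
  pc_sd <- runif(1, 0.01, 0.25)
  mk <- function(v, n, s) (B + (NC - B) * v) * (1 + rnorm(n, 0, s))
  tibble::tibble(
    plate_id = sprintf("RQ%03d", seed),
    well_role = rep(c("untreated", "dmso", "blank", "pos1", "pos2"),
                    c(6, 126, 28, 20, 20)),
    intensity = c(mk(1, 6, 0.05), mk(1, 126, cv_true),
                  B * (1 + rnorm(28, 0, 0.05)),
                  mk(pc1_v, 20, pc_sd), mk(pc2_v, 20, pc_sd)))
}

# compact screen fixtures
small_design <- function(n_cl = 3, n_anchors = 1, n_libs = 2,
                         tissues = "breast") {
  screen_design(
    cell_lines = sprintf("CL%02d", seq_len(n_cl)),
    anchors = data.frame(drug = sprintf("anc%d", seq_len(n_anchors)),
                         conc_low_log2 = 5, conc_high_log2 = 7),
    libraries = data.frame(drug = sprintf("lib%d", seq_len(n_libs))),
    tissues = tissues)
}

# fully specified noiseless truth for exact-value checks
manual_truth <- function(design, x_mid = 4, scale = 1, a_low = 0.8,
                         a_high = 0.6, synergy = NULL,
                         viability_sd = 0, intensity_sd = 0) {
  lib <- expand.grid(library_drug = design$libraries$drug,
                     cell_line = design$cell_lines,
                     stringsAsFactors = FALSE)
  lib$x_mid <- x_mid
  lib$scale <- scale
  anc <- expand.grid(conc_level = c("low", "high"),
                     anchor_drug = design$anchors$drug,
                     cell_line = design$cell_lines,
                     stringsAsFactors = FALSE)
  anc$viability <- ifelse(anc$conc_level == "low", a_low, a_high)
  anc <- merge(anc, design$anchors, by.x = "anchor_drug", by.y = "drug")
  anc$conc_log2 <- ifelse(anc$conc_level == "low", anc$conc_low_log2,
                          anc$conc_high_log2)
  ground_truth(
    library_params = lib,
    anchor_effects = anc[, c("cell_line", "anchor_drug", "conc_level",
                             "conc_log2", "viability")],
    synergy = synergy,
    noise = list(viability_sd = viability_sd, intensity_sd = intensity_sd))
}
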