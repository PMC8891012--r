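#' Ground truth for a simulated anchored screen
#'
#' Bundles the true dose-response parameters behind a simulated screen:
#' per cell line x library drug, the true sigmoid position (`x_mid`, on the
#' standardized log2 scale) and scale; per cell line x anchor concentration,
#' the true anchor viability in \[0, 1\]; per combination tuple, the injected
#' synergy shifts (`delta_pot`, log2 potency units; `delta_eff`, viability
#' units); and the noise/signal model. The true combination curve for each
#' tuple is derived on construction (see Details) and echoed in
#' `$combinations` together with the achieved true delta IC50 / delta Emax.
#'
#' @details Synergy is injected within the fitted model family so that
#' simulated combination responses remain anchor-capped sigmoids. A potency
#' shift moves the combination curve position left by `delta_pot` log2
#' units. An efficacy shift re-positions the curve so that its viability at
#' the top library dose equals the Bliss-expected top-dose viability minus
#' `delta_eff` (floored at zero when the Bliss curve leaves less than
#' `delta_eff` of viability to remove); both shifts compose. The achieved
#' true deltas are recorded, which for heavily floored efficacy injections
#' can be smaller than requested.
#'
#' @param library_params Tibble: `cell_line`, `library_drug`, `x_mid`,
#'   `scale`.
#' @param anchor_effects Tibble: `cell_line`, `anchor_drug`, `conc_level`
#'   ("low"/"high"), `conc_log2`, `viability` in \[0, 1\].
#' @param synergy Tibble: `cell_line`, `anchor_drug`, `library_drug`,
#'   `delta_pot` (>= 0), `delta_eff` (in \[0, 1\]). Tuples absent from the
#'   table are additive.
#' @param noise List: `viability_sd` (multiplicative Gaussian noise on true
#'   viability) and `intensity_sd` (additive Gaussian noise on raw
#'   intensity, the only noise blank wells see).
#' @param signal List: `blank_mean`, `negative_mean` (raw intensity units)
#'   and `pc_viability`, the true residual viabilities of the two positive
#'   controls.
#' @param seed Integer seed echoed with the truth.
#' @param top Standardized log2 top library concentration (default 9).
#' @return Object of class `ground_truth`.
#' @seealso [random_ground_truth()], [simulate_screen()]
#' @export
ground_truth <- function(library_params, anchor_effects, synergy = NULL,
                         noise = list(viability_sd = 0.05,
                                      intensity_sd = 150),
                         signal = list(blank_mean = 500,
                                       negative_mean = 50000,
                                       pc_viability = c(pos1 = 0.05,
                                                        pos2 = 0.10)),
                         seed = NA_integer_, top = 9) {
  library_params <- tibble::as_tibble(library_params)
  anchor_effects <- tibble::as_tibble(anchor_effects)
  stopifnot(all(c("cell_line", "library_drug", "x_mid", "scale") %in%
                  names(library_params)),
            all(c("cell_line", "anchor_drug", "conc_level", "viability") %in%
                  names(anchor_effects)))
  if (any(anchor_effects$viability < 0 | anchor_effects$viability > 1)) {
    stop("anchor viabilities must lie in [0, 1]")
  }
  if (is.null(synergy)) {
    synergy <- tibble::tibble(cell_line = character(),
                              anchor_drug = character(),
                              library_drug = character(),
                              delta_pot = numeric(), delta_eff = numeric())
  }
  synergy <- tibble::as_tibble(synergy)
  if (nrow(synergy)) {
    stopifnot(all(synergy$delta_pot >= 0),
              all(synergy$delta_eff >= 0 & synergy$delta_eff <= 1))
  }

  combos <- merge(
    merge(anchor_effects,
          unique(library_params[, c("cell_line", "library_drug")]),
          by = "cell_line"),
    library_params, by = c("cell_line", "library_drug"))
  combos <- merge(combos, synergy,
                  by = c("cell_line", "anchor_drug", "library_drug"),
                  all.x = TRUE)
  combos$delta_pot[is.na(combos$delta_pot)] <- 0
  combos$delta_eff[is.na(combos$delta_eff)] <- 0

  A <- combos$viability
  bliss_emax <- A * sigmoid_viability(top, combos$x_mid, combos$scale)
  x_mid_c <- combos$x_mid
  eff <- combos$delta_eff > 0
  if (any(eff)) {
    target <- pmax(bliss_emax[eff] - combos$delta_eff[eff], 0)
    ratio <- target / A[eff]
    x_mid_c[eff] <- ifelse(ratio < 1e-6, -10,
                           top - combos$scale[eff] * log(1 / ratio - 1))
  }
  x_mid_c <- pmax(x_mid_c - combos$delta_pot, -10)
  combos$x_mid_combo <- x_mid_c
  combos$upper <- A
  combos$bliss_emax_true <- bliss_emax
  combos$delta_ic50_true <- combos$x_mid - x_mid_c
  combos$delta_emax_true <-
    bliss_emax - A * sigmoid_viability(top, x_mid_c, combos$scale)

  structure(
    list(library_params = library_params, anchor_effects = anchor_effects,
         synergy = synergy,
         combinations = tibble::as_tibble(
           combos[order(combos$cell_line, combos$anchor_drug,
                        combos$library_drug, combos$conc_level), ]),
         noise = noise, signal = signal, seed = seed, top = top),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", nrow(x$library_params), "library curves,",
      nrow(x$anchor_effects), "anchor effects,",
      sum(x$synergy$delta_pot > 0 | x$synergy$delta_eff > 0),
      "synergistic tuples\n")
  invisible(x)
}

#' Draw a random ground truth for a screen design
#'
#' Samples true monotherapy curves, anchor viabilities and planted synergy
#' for every tuple of a design. Library curve positions are drawn inside
#' the tested window (`xmid_range`), reflecting screening concentrations
#' optimised to give a range of sensitivities; scales correspond to Hill
#' slopes of roughly 1-2. Anchor viabilities target moderate activity
#' (50-90% viability), the high concentration at least as active as the
#' low. A fraction of tuples receives planted synergy, split evenly
#' between potency (`delta_pot` log2 shift) and efficacy (`delta_eff`
#' top-dose viability drop); efficacy-planted tuples have their library
#' curve re-drawn from `xmid_weak_range` (weak single-agent activity), the
#' background in which efficacy gains are expressible.
#'
#' @param design A [screen_design()].
#' @param seed Integer seed.
#' @param synergy_fraction Fraction of (cell line, anchor, library) tuples
#'   with planted synergy (default 0.05).
#' @param delta_pot,delta_eff Planted shift magnitudes.
#' @param xmid_range,xmid_weak_range,scale_range,anchor_viability_range
#'   Uniform sampling ranges for the true parameters.
#' @param noise,signal As in [ground_truth()].
#' @param planted_synergy Optional tibble (`cell_line`, `anchor_drug`,
#'   `library_drug`, `delta_pot`, `delta_eff`) overriding random planting.
#' @return A `ground_truth` object.
#' @export
random_ground_truth <- function(design, seed = 1L, synergy_fraction = 0.05,
                                delta_pot = 4, delta_eff = 0.4,
                                xmid_range = c(2, 8),
                                xmid_weak_range = c(10, 13),
                                scale_range = c(0.7, 1.4),
                                anchor_viability_range = c(0.5, 0.9),
                                noise = list(viability_sd = 0.05,
                                             intensity_sd = 150),
                                signal = list(blank_mean = 500,
                                              negative_mean = 50000,
                                              pc_viability = c(pos1 = 0.05,
                                                               pos2 = 0.10)),
                                planted_synergy = NULL) {
  stopifnot(inherits(design, "screen_design"))
  set.seed(seed)

  lib <- expand.grid(library_drug = design$libraries$drug,
                     cell_line = design$cell_lines,
                     stringsAsFactors = FALSE)
  lib$x_mid <- stats::runif(nrow(lib), xmid_range[1], xmid_range[2])
  lib$scale <- stats::runif(nrow(lib), scale_range[1], scale_range[2])

  anc <- expand.grid(conc_level = c("low", "high"),
                     anchor_drug = design$anchors$drug,
                     cell_line = design$cell_lines,
                     stringsAsFactors = FALSE)
  lo <- anchor_viability_range[1]; hi <- anchor_viability_range[2]
  mid <- lo + 0.6 * (hi - lo)
  v_low <- stats::runif(nrow(anc) / 2, mid, hi)
  v_high <- stats::runif(nrow(anc) / 2, lo, v_low)
  anc$viability <- as.vector(rbind(v_low, v_high))
  anc <- merge(anc, design$anchors, by.x = "anchor_drug", by.y = "drug")
  anc$conc_log2 <- ifelse(anc$conc_level == "low", anc$conc_low_log2,
                          anc$conc_high_log2)
  anc <- anc[, c("cell_line", "anchor_drug", "conc_level", "conc_log2",
                 "viability")]

  if (is.null(planted_synergy)) {
    tuples <- design_plates(design)[, c("cell_line", "anchor_drug",
                                        "library_drug")]
    n_syn <- round(synergy_fraction * nrow(tuples))
    idx <- sample(nrow(tuples), n_syn)
    planted_synergy <- tuples[idx, ]
    kind <- rep(c("pot", "eff"), length.out = n_syn)
    planted_synergy$delta_pot <- ifelse(kind == "pot", delta_pot, 0)
    planted_synergy$delta_eff <- ifelse(kind == "eff", delta_eff, 0)
  }
  planted_synergy <- tibble::as_tibble(planted_synergy)

  # efficacy synergy needs residual viability at top dose: weak library
  if (nrow(planted_synergy)) {
    weak <- unique(planted_synergy[planted_synergy$delta_eff > 0,
                                   c("cell_line", "library_drug")])
    if (nrow(weak)) {
      key <- paste(lib$cell_line, lib$library_drug)
      sel <- key %in% paste(weak$cell_line, weak$library_drug)
      lib$x_mid[sel] <- stats::runif(sum(sel), xmid_weak_range[1],
                                     xmid_weak_range[2])
    }
  }

  ground_truth(library_params = lib, anchor_effects = anc,
               synergy = planted_synergy, noise = noise, signal = signal,
               seed = seed, top = max(design$libraries$top_log2))
}

# deterministic per-plate RNG stream (32-bit safe)
plate_seed <- function(seed, plate_index) {
  as.integer((as.double(seed) %% 2147483647) * 1009 + plate_index) %%
    2147483647L
}

#' Simulate an anchored combination screen
#'
#' Generates one plate of raw well intensities per
#' (cell line, anchor, library) triple: the full control census, five
#' replicates of each anchor concentration alone, four replicates of the
#' 7-point library dose response, and a single combination dose response
#' per anchor concentration. Raw intensity is
#' `blank_mean + (negative_mean - blank_mean) * viability * (1 + e)` with
#' multiplicative Gaussian viability noise `e` plus additive intensity
#' noise; blank wells carry only additive noise. Each plate uses its own
#' RNG stream derived from `(seed, plate index)`, so identical seeds give
#' byte-identical output and plates are independently reproducible.
#'
#' @param design A [screen_design()].
#' @param truth A [ground_truth()] covering every cell line/drug in the
#'   design.
#' @param seed Integer seed for the noise streams.
#' @return List of class `screen_sim`: `wells` (one row per well), `truth`
#'   echo and `design`.
#' @export
simulate_screen <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "screen_design"),
            inherits(truth, "ground_truth"))
  plates <- design_plates(design)

  lib_key <- paste(truth$library_params$cell_line,
                   truth$library_params$library_drug)
  miss <- setdiff(paste(plates$cell_line, plates$library_drug), lib_key)
  if (length(miss)) {
    stop("ground truth missing library curve for: ", miss[1])
  }
  anc_key <- paste(truth$anchor_effects$cell_line,
                   truth$anchor_effects$anchor_drug)
  miss <- setdiff(paste(plates$cell_line, plates$anchor_drug), anc_key)
  if (length(miss)) {
    stop("ground truth missing anchor effect for: ", miss[1])
  }

  B <- truth$signal$blank_mean
  NC <- truth$signal$negative_mean
  pc <- truth$signal$pc_viability
  sd_v <- truth$noise$viability_sd
  sd_i <- truth$noise$intensity_sd
  census <- design$census
  n_rep <- design$n_rep

  lp <- truth$library_params
  ae <- truth$anchor_effects
  ct <- truth$combinations

  out <- vector("list", nrow(plates))
  for (i in seq_len(nrow(plates))) {
    pl <- plates[i, ]
    doses <- library_doses(
      design$libraries$top_log2[design$libraries$drug == pl$library_drug])
    p <- lp[lp$cell_line == pl$cell_line &
              lp$library_drug == pl$library_drug, ]
    a <- ae[ae$cell_line == pl$cell_line &
              ae$anchor_drug == pl$anchor_drug, ]
    a <- a[order(match(a$conc_level, c("low", "high"))), ]
    cc <- ct[ct$cell_line == pl$cell_line &
               ct$anchor_drug == pl$anchor_drug &
               ct$library_drug == pl$library_drug, ]
    cc <- cc[order(match(cc$conc_level, c("low", "high"))), ]

    role <- c(rep("untreated", census["untreated"]),
              rep("dmso", census["dmso"]),
              rep("blank", census["blank"]),
              rep("pos1", census["pos1"]),
              rep("pos2", census["pos2"]),
              rep("anchor", 2 * n_rep["anchor"]),
              rep("library", n_rep["library"] * length(doses)),
              rep("combination", 2 * length(doses)))
    v_true <- c(rep(1, census["untreated"] + census["dmso"]),
                rep(0, census["blank"]),
                rep(pc["pos1"], census["pos1"]),
                rep(pc["pos2"], census["pos2"]),
                rep(a$viability, each = n_rep["anchor"]),
                rep(sigmoid_viability(doses, p$x_mid, p$scale),
                    times = n_rep["library"]),
                as.vector(vapply(seq_len(nrow(cc)), function(j) {
                  sigmoid_viability(doses, cc$x_mid_combo[j], cc$scale[j],
                                    cc$upper[j])
                }, numeric(length(doses)))))
    anchor_conc <- rep(NA_real_, length(role))
    anchor_conc[role == "anchor"] <- rep(a$conc_log2, each = n_rep["anchor"])
    anchor_conc[role == "combination"] <- rep(cc$conc_log2,
                                              each = length(doses))
    lib_conc <- rep(NA_real_, length(role))
    lib_conc[role == "library"] <- rep(doses, times = n_rep["library"])
    lib_conc[role == "combination"] <- rep(doses, 2)
    replicate <- stats::ave(seq_along(role),
                            paste(role, anchor_conc, lib_conc),
                            FUN = seq_along)

    v_true <- unname(v_true)
    set.seed(plate_seed(seed, i))
    v_obs <- v_true * (1 + stats::rnorm(length(v_true), 0, sd_v))
    intensity <- B + (NC - B) * v_obs +
      stats::rnorm(length(v_true), 0, sd_i)

    out[[i]] <- tibble::tibble(
      plate_id = pl$plate_id, cell_line = pl$cell_line,
      tissue = unname(design$tissues[pl$cell_line]),
      well_role = role,
      anchor_drug = ifelse(role %in% c("anchor", "combination"),
                           pl$anchor_drug, NA_character_),
      anchor_conc_log2 = anchor_conc,
      library_drug = ifelse(role %in% c("library", "combination"),
                            pl$library_drug, NA_character_),
      library_conc_log2 = lib_conc,
      replicate = as.integer(replicate),
      intensity = intensity)
  }

  structure(list(wells = dplyr::bind_rows(out), truth = truth,
                 design = design),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated screen:", length(unique(x$wells$plate_id)), "plates,",
      nrow(x$wells), "wells (seed", x$truth$seed, ")\n")
  invisible(x)
}

#' Simulate binary molecular features and expression with planted effects
#'
#' Builds a MOBEM-style binary feature matrix (cell lines x features) in
#' which designated features are associated with designated combination
#' responses at a stated effect size, plus background features independent
#' of response, and a continuous expression matrix with designated outlier
#' cell lines beyond |z| = 2 (to exercise expression binarization).
#'
#' @param cell_lines Character vector of cell-line identifiers.
#' @param planted Optional tibble: `feature`, `combination`, `effect_size`
#'   (mean response shift in units of within-group standard deviation) and
#'   optionally `n_pos` (feature-positive count, default half).
#' @param n_background_features Number of response-independent binary
#'   features (prevalence uniform on 0.2-0.8).
#' @param seed Integer seed.
#' @param expr_genes Number of expression genes (standard normal).
#' @param expr_outliers Number of planted expression outliers (alternating
#'   up/down, magnitude 6 marginal standard deviations).
#' @return List: `features` (binary matrix), `expression` (numeric
#'   matrix), `truth` (planted assignments and outliers).
#' @seealso [simulate_biomarker_responses()]
#' @export
simulate_features <- function(cell_lines, planted = NULL,
                              n_background_features = 50, seed = 1L,
                              expr_genes = 20, expr_outliers = 2) {
  set.seed(seed)
  n <- length(cell_lines)
  feats <- list()
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("feature", "combination", "effect_size") %in%
                    names(planted)))
    if (!"n_pos" %in% names(planted)) planted$n_pos <- round(n / 2)
    planted$positives <- lapply(planted$n_pos, function(k) {
      sort(sample(cell_lines, k))
    })
    for (j in seq_len(nrow(planted))) {
      k <- planted$n_pos[j]
      if (k < 2 || k > n - 2) {
        warning("planted feature '", planted$feature[j],
                "' present in ", k, " of ", n,
                " cell lines: association untestable")
      }
      col <- as.integer(cell_lines %in% planted$positives[[j]])
      feats[[planted$feature[j]]] <- col
    }
  }
  if (n_background_features > 0) {
    prev <- stats::runif(n_background_features, 0.2, 0.8)
    for (j in seq_len(n_background_features)) {
      feats[[sprintf("bg%03d", j)]] <- stats::rbinom(n, 1, prev[j])
    }
  }
  features <- do.call(cbind, feats)
  rownames(features) <- cell_lines

  expression <- matrix(stats::rnorm(n * expr_genes), nrow = n,
                       dimnames = list(cell_lines,
                                       sprintf("gene%03d",
                                               seq_len(expr_genes))))
  outliers <- NULL
  if (expr_outliers > 0) {
    gi <- sample(expr_genes, expr_outliers, replace = expr_genes <
                   expr_outliers)
    ci <- sample(n, expr_outliers, replace = n < expr_outliers)
    dir <- rep(c(1, -1), length.out = expr_outliers)
    for (j in seq_len(expr_outliers)) {
      expression[ci[j], gi[j]] <- 6 * dir[j]
    }
    outliers <- tibble::tibble(gene = colnames(expression)[gi],
                               cell_line = cell_lines[ci],
                               direction = ifelse(dir > 0, "up", "down"))
  }
  list(features = features, expression = expression,
       truth = list(planted = planted, outliers = outliers, seed = seed))
}

#' Simulate response vectors carrying planted feature associations
#'
#' For each planted (feature, combination, effect size), draws a standard
#' normal response across cell lines and shifts feature-positive lines by
#' `effect_size` within-group standard deviations; optional additional
#' null response columns carry no association.
#'
#' @param features Binary feature matrix from [simulate_features()].
#' @param planted Tibble as in [simulate_features()].
#' @param n_null Extra response columns independent of all features.
#' @param sigma Within-group standard deviation.
#' @param seed Integer seed.
#' @return Numeric matrix, cell lines x response columns.
#' @export
simulate_biomarker_responses <- function(features, planted, n_null = 0,
                                         sigma = 1, seed = 1L) {
  set.seed(seed)
  planted <- tibble::as_tibble(planted)
  n <- nrow(features)
  cols <- list()
  for (j in seq_len(nrow(planted))) {
    y <- stats::rnorm(n, 0, sigma)
    y <- y + planted$effect_size[j] * sigma * features[, planted$feature[j]]
    cols[[planted$combination[j]]] <- y
  }
  if (n_null > 0) {
    for (j in seq_len(n_null)) {
      cols[[sprintf("null%03d", j)]] <- stats::rnorm(n, 0, sigma)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(features)
  m
}

#' Write / read simulated plate tables
#'
#' Plate tables are tab-delimited text with one row per well; the ground
#' truth is written as sidecar tables (`*_truth_*.tsv`).
#'
#' @param sim A `screen_sim`.
#' @param dir Output directory (created if needed).
#' @return `write_screen` returns the directory invisibly; `read_wells`
#'   returns a well tibble.
#' @export
write_screen <- function(sim, dir) {
  stopifnot(inherits(sim, "screen_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$wells, file.path(dir, "wells.tsv"))
  readr::write_tsv(sim$truth$library_params,
                   file.path(dir, "wells_truth_library.tsv"))
  readr::write_tsv(sim$truth$anchor_effects,
                   file.path(dir, "wells_truth_anchors.tsv"))
  readr::write_tsv(sim$truth$combinations,
                   file.path(dir, "wells_truth_combinations.tsv"))
  invisible(dir)
}

#' @rdname write_screen
#' @param path Path to a wells table written by [write_screen()].
#' @export
read_wells <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    plate_id = "c", cell_line = "c", tissue = "c",
                    well_role = "c", anchor_drug = "c",
                    library_drug = "c", replicate = "i",
                    .default = "d"))
}
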