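#' Default pipeline configuration
#'
#' All analysis thresholds with their standard defaults (CV 0.18,
#' plate/set Z-factors 0.3/0.4, NC:PC ratio 4, RMSE 0.2, delta IC50 3,
#' delta Emax 0.2, qualifying IC50 10, biomarker p 0.001 / FDR 0.05 /
#' Glass delta 1, enrichment p 0.005, interactome confidence 0.5),
#' simulation settings and the seed. Configs round-trip losslessly
#' through YAML.
#'
#' @param seed Integer seed.
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_cell_lines = 12L, n_anchors = 2L, n_libraries = 4L,
      tissues = c("breast", "colon", "pancreas"),
      synergy_fraction = 0.05, delta_pot = 4, delta_eff = 0.4,
      noise_viability_sd = 0.05, noise_intensity_sd = 150,
      n_background_features = 50L, n_planted_biomarkers = 1L,
      biomarker_effect_size = 2),
    qc = list(cv_max = 0.18, z_min_plate = 0.3, z_min_set = 0.4,
              pc_ratio_min = 4),
    fit = list(rmse_max = 0.2, free_scale = FALSE),
    synergy = list(delta_ic50_min = 3, delta_emax_min = 0.2,
                   ic50_qualify_max = 10),
    biomarkers = list(p_max = 0.001, fdr_max = 0.05, glass_min = 1,
                      fdr_family = "context_metric", min_group = 3),
    enrichment = list(p_max = 0.005, fdr_max = 0.05),
    network = list(confidence_min = 0.5, edges_file = NULL,
                   n_perm = 20L)),
    class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Select a cell-line context by predicate
#'
#' Evaluates a predicate over a cell-line annotation table (tissue labels
#' and binary feature columns) and returns the matching cell lines — the
#' mechanism behind molecular "baskets" such as KRAS-mutant colon or MSS
#' colon.
#'
#' @param cell_line_table Data frame with a `cell_line` column plus
#'   annotation columns.
#' @param predicate A one-sided formula or string, e.g.
#'   `~ tissue == "colon" & KRAS_mut == 1`.
#' @return Character vector of cell lines satisfying the predicate.
#' @export
define_context <- function(cell_line_table, predicate) {
  stopifnot("cell_line" %in% names(cell_line_table))
  expr <- if (inherits(predicate, "formula")) {
    predicate[[2]]
  } else {
    str2lang(predicate)
  }
  vars <- all.vars(expr)
  unknown <- setdiff(vars, names(cell_line_table))
  if (length(unknown)) {
    stop("unknown column(s) in predicate: ",
         paste(unknown, collapse = ", "))
  }
  keep <- eval(expr, envir = cell_line_table, enclos = parent.frame())
  keep[is.na(keep)] <- FALSE
  lines <- cell_line_table$cell_line[keep]
  if (length(lines) == 0) stop("predicate selects no cell lines")
  lines
}

# build the simulated study a config describes
simulate_from_config <- function(config) {
  sim <- config$simulate
  seed <- config$seed
  n_cl <- sim$n_cell_lines
  tissues <- rep(sim$tissues, length.out = n_cl)
  cell_lines <- sprintf("CL%02d", seq_len(n_cl))
  design <- screen_design(
    cell_lines = cell_lines,
    anchors = data.frame(drug = sprintf("anchor%02d",
                                        seq_len(sim$n_anchors)),
                         conc_low_log2 = 5, conc_high_log2 = 7),
    libraries = data.frame(drug = sprintf("lib%02d",
                                          seq_len(sim$n_libraries))),
    tissues = tissues)

  set.seed(seed)
  combos <- expand.grid(anchor_drug = design$anchors$drug,
                        library_drug = design$libraries$drug,
                        stringsAsFactors = FALSE)
  planted_bm <- NULL
  planted_syn <- NULL
  if (sim$n_planted_biomarkers > 0) {
    sel <- combos[sample(nrow(combos), sim$n_planted_biomarkers), ]
    planted_bm <- tibble::tibble(
      feature = sprintf("planted%02d", seq_len(nrow(sel))),
      anchor_drug = sel$anchor_drug, library_drug = sel$library_drug,
      combination = paste0(sel$anchor_drug, "+", sel$library_drug),
      effect_size = sim$biomarker_effect_size)
  }
  feats <- simulate_features(
    cell_lines,
    planted = if (is.null(planted_bm)) NULL else
      planted_bm[, c("feature", "combination", "effect_size")],
    n_background_features = sim$n_background_features,
    seed = seed + 101L)
  # feature-positive cell lines respond synergistically to the planted
  # combination: the planted biomarker is carried by the screen itself
  if (!is.null(planted_bm)) {
    rows <- list()
    for (j in seq_len(nrow(planted_bm))) {
      pos <- rownames(feats$features)[
        feats$features[, planted_bm$feature[j]] == 1]
      if (length(pos)) {
        rows[[j]] <- tibble::tibble(
          cell_line = pos, anchor_drug = planted_bm$anchor_drug[j],
          library_drug = planted_bm$library_drug[j],
          delta_pot = 0, delta_eff = sim$delta_eff)
      }
    }
    planted_syn <- dplyr::bind_rows(rows)
  }
  truth <- random_ground_truth(
    design, seed = seed + 7L,
    synergy_fraction = sim$synergy_fraction,
    delta_pot = sim$delta_pot, delta_eff = sim$delta_eff,
    noise = list(viability_sd = sim$noise_viability_sd,
                 intensity_sd = sim$noise_intensity_sd),
    planted_synergy = planted_syn)
  screen <- simulate_screen(design, truth, seed = seed)
  list(screen = screen, features = feats, planted_biomarkers = planted_bm)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> QC -> fit/synergy -> biomarkers (-> network)
#' into a run directory of delimited tables plus a JSON manifest with the
#' seed and per-stage counts (plates passing QC, tuples excluded by
#' curve-fit validity, synergy calls, significant associations). Stages
#' whose outputs already exist and are newer than their inputs are
#' skipped unless `force = TRUE`. Reruns with the same config and seed
#' are byte-identical.
#'
#' @param config A [default_config()]-style `run_config`.
#' @param out_dir Run directory (created).
#' @param force Recompute stages even when cached outputs exist.
#' @return The manifest (list), invisibly; tables are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(wells = file.path(out_dir, "wells.tsv"),
                qc = file.path(out_dir, "qc.tsv"),
                tuples = file.path(out_dir, "synergy_tuples.tsv"),
                pairs = file.path(out_dir, "synergy_pairs.tsv"),
                assoc = file.path(out_dir, "associations.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  fresh <- function(out, dep) {
    !force && file.exists(out) &&
      (!file.exists(dep) || file.mtime(out) >= file.mtime(dep))
  }
  manifest <- list(package = "anchorscreen",
                   version = as.character(utils::packageVersion(
                     "anchorscreen")),
                   seed = config$seed, stages = list())

  # simulate (always rebuilt in memory; tables cached on disk)
  simdat <- simulate_from_config(config)
  wells <- simdat$screen$wells
  if (!fresh(paths$wells, "")) {
    write_screen(simdat$screen, out_dir)
  }
  manifest$stages$simulate <- list(
    plates = length(unique(wells$plate_id)), wells = nrow(wells))

  # qc
  thr <- qc_thresholds(cv_max = config$qc$cv_max,
                       z_min_plate = config$qc$z_min_plate,
                       z_min_set = config$qc$z_min_set,
                       pc_ratio_min = config$qc$pc_ratio_min)
  qc <- qc_screen(wells, thr)
  readr::write_tsv(qc, paths$qc)
  manifest$stages$qc <- list(plates = nrow(qc),
                             passed = sum(qc$pass),
                             mean_z = attr(qc, "mean_z"),
                             set_pass = attr(qc, "set_pass"))

  # fit + synergy
  sth <- synergy_thresholds(
    delta_ic50_min = config$synergy$delta_ic50_min,
    delta_emax_min = config$synergy$delta_emax_min,
    ic50_qualify_max = config$synergy$ic50_qualify_max)
  scored <- score_screen(wells, qc = qc, thresholds = sth,
                         rmse_max = config$fit$rmse_max,
                         free_scale = config$fit$free_scale)
  readr::write_tsv(scored$tuples, paths$tuples)
  readr::write_tsv(scored$pairs, paths$pairs)
  manifest$stages$synergy <- list(
    tuples = nrow(scored$tuples),
    excluded = sum(scored$tuples$excluded),
    pairs = nrow(scored$pairs),
    synergistic = sum(scored$pairs$synergy, na.rm = TRUE))

  # biomarkers
  responses <- build_response_matrix(scored$tuples)
  bm <- config$biomarkers
  tissue <- simdat$screen$design$tissues
  assoc <- run_biomarker_scan(responses, simdat$features$features,
                              tissue = tissue, p_max = bm$p_max,
                              fdr_max = bm$fdr_max,
                              glass_min = bm$glass_min,
                              fdr_family = bm$fdr_family,
                              min_group = bm$min_group)
  readr::write_tsv(assoc, paths$assoc)
  manifest$stages$biomarkers <- list(
    tests = nrow(assoc), significant = sum(assoc$significant,
                                           na.rm = TRUE))

  # network (optional)
  if (!is.null(config$network$edges_file)) {
    edges <- read_edge_list(config$network$edges_file)
    g <- build_interactome(edges,
                           confidence_min = config$network$confidence_min)
    manifest$stages$network <- list(nodes = igraph::vcount(g),
                                    edges = igraph::ecount(g))
  }

  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
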