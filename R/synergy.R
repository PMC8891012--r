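#' Synergy classification thresholds
#'
#' @param delta_ic50_min Minimum potency shift (log2 units; 3 equals an
#'   8-fold IC50 shift).
#' @param delta_emax_min Minimum efficacy shift (viability units; 0.2
#'   equals a 20% viability shift).
#' @param ic50_qualify_max Qualifying gate: the combination IC50 must fall
#'   below this standardized log2 value — 10 is twice the highest screened
#'   library concentration (top = 9).
#' @return Named list of thresholds.
#' @export
synergy_thresholds <- function(delta_ic50_min = 3, delta_emax_min = 0.2,
                               ic50_qualify_max = 10) {
  list(delta_ic50_min = delta_ic50_min, delta_emax_min = delta_emax_min,
       ic50_qualify_max = ic50_qualify_max)
}

#' Bliss-expected combination response
#'
#' Under Bliss independence every point on the expected combination curve
#' is the product of the anchor viability and the corresponding point on
#' the library dose-response curve. With a lower asymptote of 0, scaling
#' the library curve by `A` leaves its half-point (measured between zero
#' and `A`) unchanged, so the Bliss IC50 equals the library `x_mid`; the
#' Bliss Emax is `A` times the library Emax.
#'
#' @param anchor_viability Anchor viability `A` in (0, 1].
#' @param library_fit A valid library `curve_fit`.
#' @return List of class `bliss_curve`: `anchor_viability`,
#'   `ic50_log2`, `emax`, and `predict(x)`.
#' @export
bliss_expected <- function(anchor_viability, library_fit) {
  stopifnot(inherits(library_fit, "curve_fit"),
            anchor_viability > 0, anchor_viability <= 1)
  if (!library_fit$valid) stop("library fit must be valid")
  A <- anchor_viability
  structure(
    list(anchor_viability = A,
         ic50_log2 = library_fit$x_mid,
         emax = A * library_fit$emax,
         predict = function(x) A * predict(library_fit, x)),
    class = "bliss_curve")
}

#' Synergy metrics for one anchored combination tuple
#'
#' Computes the potency and efficacy shifts of an observed combination
#' beyond Bliss independence: `delta_ic50 = Bliss IC50 - combination IC50`
#' (log2 units; positive = potency gain) and
#' `delta_emax = Bliss Emax - combination Emax` (viability units; positive
#' = efficacy gain). A tuple `qualifies` when the combination IC50 is
#' below `ic50_qualify_max` (in range), and is called synergistic when it
#' qualifies and either shift reaches its threshold.
#'
#' @inheritParams bliss_expected
#' @param combo_fit A valid anchor-capped combination `curve_fit`.
#' @param thresholds A [synergy_thresholds()] list.
#' @return One-row tibble with the anchor viability, Bliss and combination
#'   IC50/Emax, both deltas, `qualifies` and `synergy`.
#' @export
synergy_metrics <- function(anchor_viability, library_fit, combo_fit,
                            thresholds = synergy_thresholds()) {
  stopifnot(inherits(combo_fit, "curve_fit"))
  if (!combo_fit$valid) stop("combination fit must be valid")
  bliss <- bliss_expected(anchor_viability, library_fit)
  delta_ic50 <- bliss$ic50_log2 - combo_fit$ic50_log2
  delta_emax <- bliss$emax - combo_fit$emax
  qualifies <- combo_fit$ic50_log2 < thresholds$ic50_qualify_max
  tibble::tibble(
    A = anchor_viability,
    bliss_ic50_log2 = bliss$ic50_log2, bliss_emax = bliss$emax,
    combo_ic50_log2 = combo_fit$ic50_log2, combo_emax = combo_fit$emax,
    delta_ic50 = delta_ic50, delta_emax = delta_emax,
    qualifies = qualifies,
    synergy = qualifies & (delta_ic50 >= thresholds$delta_ic50_min |
                             delta_emax >= thresholds$delta_emax_min))
}

#' Aggregate replicate synergy calls
#'
#' A tuple is synergistic if half or more of its replicate measurements
#' showed synergy.
#'
#' @param calls Logical vector of replicate-level calls (length >= 1).
#' @return Logical.
#' @export
aggregate_replicates <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("no replicate calls to aggregate")
  mean(calls) >= 0.5
}

#' Aggregate anchor-concentration synergy calls
#'
#' A combination-cell line pair is synergistic if synergy was observed at
#' either anchor concentration. A missing anchor is treated as
#' non-synergistic (single-anchor call); both missing is an error.
#'
#' @param low_call,high_call Logical calls at the two anchor
#'   concentrations (`NA` = not evaluated).
#' @return Logical.
#' @export
aggregate_anchors <- function(low_call, high_call) {
  if (is.na(low_call) && is.na(high_call)) {
    stop("no anchor concentration evaluated")
  }
  isTRUE(low_call) || isTRUE(high_call)
}

#' Screen-versus-screen reproducibility
#'
#' Treats the first screen as ground truth, counts
#' true/false positive/negative synergy calls over the matched keys, and
#' reports `F-score = TP / (TP + 0.5 (FP + FN))`, recall and precision,
#' plus the Pearson correlation between screens for each shared numeric
#' response metric.
#'
#' @param screen1,screen2 Tibbles with key columns, a logical `synergy`
#'   column, and optionally shared numeric metric columns.
#' @param by Key columns to match on.
#' @param group Optional grouping column (e.g. `"tissue"`) for per-group
#'   reports.
#' @return Tibble with one row per group: confusion counts, `f_score`,
#'   `recall`, `precision`, and one `cor_<metric>` column per shared
#'   metric.
#' @export
reproducibility <- function(screen1, screen2,
                            by = c("cell_line", "anchor_drug",
                                   "library_drug"),
                            group = NULL) {
  stopifnot("synergy" %in% names(screen1), "synergy" %in% names(screen2))
  m <- dplyr::inner_join(screen1, screen2, by = by,
                         suffix = c(".1", ".2"))
  if (nrow(m) == 0) stop("screens share no keys")
  metrics <- intersect(
    names(screen1)[vapply(screen1, is.numeric, logical(1))],
    names(screen2)[vapply(screen2, is.numeric, logical(1))])
  metrics <- setdiff(metrics, by)
  g <- if (is.null(group)) {
    rep("all", nrow(m))
  } else if (group %in% names(m)) {
    m[[group]]
  } else {
    m[[paste0(group, ".1")]]
  }

  parts <- split(m, g)
  dplyr::bind_rows(lapply(names(parts), function(nm) {
    d <- parts[[nm]]
    tp <- sum(d$synergy.1 & d$synergy.2)
    fp <- sum(!d$synergy.1 & d$synergy.2)
    tn <- sum(!d$synergy.1 & !d$synergy.2)
    fn <- sum(d$synergy.1 & !d$synergy.2)
    row <- tibble::tibble(
      group = nm, n = nrow(d), tp = tp, fp = fp, tn = tn, fn = fn,
      f_score = tp / (tp + 0.5 * (fp + fn)),
      recall = tp / (tp + fn), precision = tp / (tp + fp))
    for (mt in metrics) {
      row[[paste0("cor_", mt)]] <-
        stats::cor(d[[paste0(mt, ".1")]], d[[paste0(mt, ".2")]],
                   use = "complete.obs")
    }
    row
  }))
}

#' Synergy rates by group
#'
#' Per-group count of evaluable pairs, synergistic pairs and synergy rate;
#' denominators count only evaluable (non-missing) calls. `min_rate`
#' restricts the table to groups at or above a rate threshold (e.g.
#' combinations synergistic in at least 20% of cell lines).
#'
#' @param calls Tibble with a logical `synergy` column.
#' @param by Grouping column name(s).
#' @param min_rate Optional minimum rate filter.
#' @return Tibble: grouping columns, `n`, `n_synergistic`, `rate`.
#' @export
synergy_rate <- function(calls, by, min_rate = NULL) {
  stopifnot("synergy" %in% names(calls))
  out <- dplyr::summarise(
    dplyr::group_by(calls, dplyr::across(dplyr::all_of(by))),
    n = sum(!is.na(.data$synergy)),
    n_synergistic = sum(.data$synergy, na.rm = TRUE),
    .groups = "drop")
  out <- out[out$n > 0, ]
  out$rate <- out$n_synergistic / out$n
  if (!is.null(min_rate)) out <- out[out$rate >= min_rate, ]
  out
}

#' Score an anchored screen: fits, Bliss metrics and synergy calls
#'
#' Full per-plate analysis of a normalized (or raw) well table: per plate,
#' intensities are normalized by the plate's blank/negative means, the
#' anchor viability is the mean of the five anchor-only replicates per
#' concentration, the library monotherapy curve is fitted to
#' replicate-averaged viabilities with upper asymptote 1, and each
#' combination dose response is fitted capped at the anchor viability with
#' the library scale tied. Tuples whose library or combination fit is
#' invalid (RMSE > `rmse_max` or non-convergent) are excluded from synergy
#' calling and logged. Pair-level calls aggregate replicates (majority)
#' and then anchor concentrations (either).
#'
#' @param wells Well table (one or more plates) with raw `intensity`.
#' @param qc Optional [qc_screen()] result; failed plates are dropped.
#' @param thresholds A [synergy_thresholds()] list.
#' @param rmse_max RMSE validity threshold for fits.
#' @param free_scale Passed to [fit_combination()].
#' @return List of class `synergy_screen`: `tuples` (one row per anchor
#'   concentration x library x cell line with fit parameters and
#'   [synergy_metrics()] columns, including excluded tuples flagged with a
#'   reason), `pairs` (aggregated combination-cell line calls with
#'   `synergy_low`, `synergy_high`, `synergy`, `dual_anchor`), and
#'   `excluded` counts.
#' @export
score_screen <- function(wells, qc = NULL,
                         thresholds = synergy_thresholds(),
                         rmse_max = 0.2, free_scale = FALSE) {
  if (!is.null(qc)) {
    keep <- qc$plate_id[qc$pass]
    wells <- wells[wells$plate_id %in% keep, ]
    if (nrow(wells) == 0) stop("no plates passed QC")
  }
  if (!"viability" %in% names(wells)) wells <- normalize_wells(wells)

  rows <- list()
  for (id in unique(wells$plate_id)) {
    w <- wells[wells$plate_id == id, ]
    lib_drug <- stats::na.omit(unique(w$library_drug))[1]
    anc_drug <- stats::na.omit(unique(w$anchor_drug))[1]
    cl <- w$cell_line[1]

    lw <- w[w$well_role == "library", ]
    lib_avg <- dplyr::summarise(
      dplyr::group_by(lw, dose = .data$library_conc_log2),
      v = mean(.data$viability), .groups = "drop")
    lib_avg <- lib_avg[order(lib_avg$dose), ]
    lib_fit <- fit_library(lib_avg$dose, lib_avg$v, rmse_max = rmse_max)

    concs <- sort(stats::na.omit(unique(w$anchor_conc_log2)))
    for (ci in seq_along(concs)) {
      conc <- concs[ci]
      level <- c("low", "high")[ci]
      aw <- w[w$well_role == "anchor" &
                w$anchor_conc_log2 == conc, ]
      A <- suppressWarnings(anchor_viability(aw$viability))
      cw <- w[w$well_role == "combination" &
                w$anchor_conc_log2 == conc, ]
      cw <- cw[order(cw$library_conc_log2), ]

      base <- tibble::tibble(
        plate_id = id, cell_line = cl,
        tissue = if ("tissue" %in% names(w)) w$tissue[1] else NA_character_,
        anchor_drug = anc_drug, anchor_conc_level = level,
        anchor_conc_log2 = conc, library_drug = lib_drug,
        library_ic50_log2 = lib_fit$x_mid, library_scale = lib_fit$scale,
        library_emax = lib_fit$emax, library_rmse = lib_fit$rmse)

      if (is.na(A)) {
        rows[[length(rows) + 1]] <-
          dplyr::mutate(base, excluded = TRUE,
                        reason = "anchor viability missing")
        next
      }
      if (!lib_fit$valid) {
        rows[[length(rows) + 1]] <-
          dplyr::mutate(base, A = A, excluded = TRUE,
                        reason = "invalid library fit")
        next
      }
      combo_fit <- fit_combination(cw$library_conc_log2, cw$viability,
                                   anchor_viability = A,
                                   library_fit = lib_fit,
                                   free_scale = free_scale,
                                   rmse_max = rmse_max)
      if (!combo_fit$valid) {
        rows[[length(rows) + 1]] <-
          dplyr::mutate(base, A = A, combo_rmse = combo_fit$rmse,
                        excluded = TRUE, reason = "invalid combination fit")
        next
      }
      met <- synergy_metrics(A, lib_fit, combo_fit, thresholds)
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(base, met,
                         tibble::tibble(combo_rmse = combo_fit$rmse,
                                        excluded = FALSE,
                                        reason = NA_character_))
    }
  }
  tuples <- dplyr::bind_rows(rows)

  ev <- tuples[!tuples$excluded, ]
  # majority vote over replicate plates of the same tuple, then either-anchor
  rep_calls <- dplyr::summarise(
    dplyr::group_by(ev, .data$cell_line, .data$tissue, .data$anchor_drug,
                    .data$library_drug, .data$anchor_conc_level),
    call = aggregate_replicates(.data$synergy), .groups = "drop")
  pairs <- tidyr::pivot_wider(rep_calls, names_from = "anchor_conc_level",
                              values_from = "call")
  for (lv in c("low", "high")) {
    if (!lv %in% names(pairs)) pairs[[lv]] <- NA
  }
  pairs$synergy <- mapply(function(l, h) {
    if (is.na(l) && is.na(h)) NA else aggregate_anchors(l, h)
  }, pairs$low, pairs$high)
  pairs$dual_anchor <- !is.na(pairs$low) & !is.na(pairs$high) &
    pairs$low & pairs$high
  pairs$single_anchor_only <- xor(is.na(pairs$low), is.na(pairs$high))
  names(pairs)[names(pairs) == "low"] <- "synergy_low"
  names(pairs)[names(pairs) == "high"] <- "synergy_high"

  structure(list(tuples = tuples, pairs = pairs,
                 excluded = table(tuples$reason[tuples$excluded])),
            class = "synergy_screen")
}

#' @export
print.synergy_screen <- function(x, ...) {
  n_ev <- sum(!x$tuples$excluded)
  cat(sprintf(
    "Scored screen: %d tuples (%d excluded), %d pairs, %d synergistic\n",
    nrow(x$tuples), sum(x$tuples$excluded), nrow(x$pairs),
    sum(x$pairs$synergy, na.rm = TRUE)))
  invisible(x)
}
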