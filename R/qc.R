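#' Normalize raw intensity to relative viability
#'
#' `(intensity - B) / (NC - B)` where `B` is the mean of the blank
#' (medium-only) wells and `NC` the mean of the DMSO-treated negative
#' controls. Values may fall outside \[0, 1\] before curve fitting; the
#' fitted model, not the data, enforces the viability range. The
#' transformation is affine-invariant: rescaling and shifting all
#' intensities leaves viabilities unchanged.
#'
#' @param intensity Raw well intensity (vectorized).
#' @param blank_mean Mean blank intensity `B`.
#' @param negative_mean Mean negative-control intensity `NC`; must exceed
#'   `blank_mean`.
#' @return Relative viability.
#' @examples
#' normalize_viability(5000, 200, 9800)  # 0.5
#' @export
normalize_viability <- function(intensity, blank_mean, negative_mean) {
  if (negative_mean <= blank_mean) {
    stop("plate invalid: negative-control mean does not exceed blank mean")
  }
  (intensity - blank_mean) / (negative_mean - blank_mean)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean (sd_N / mu_N). Used on
#' the DMSO-treated negative controls of each plate.
#'
#' @param values At least 2 numeric values with non-zero mean.
#' @return Nonnegative real (`NA` with a warning if the mean is 0).
#' @examples
#' coefficient_of_variation(c(0.9, 1, 1.1))  # 0.1
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) {
    warning("degenerate negatives: mean is zero, CV undefined")
    return(NA_real_)
  }
  stats::sd(values) / m
}

#' Z-factor of a control pair
#'
#' `1 - 3 * (sd_P + sd_N) / |mu_P - mu_N|`, the screening-window statistic
#' comparing positive/negative control separation to their spreads.
#' Unbounded below; equals 1 only for perfectly tight, separated controls.
#' Symmetric in the two groups. When the group means coincide the
#' statistic is undefined and `NA` is returned (treated as a failure by
#' [qc_plate()]).
#'
#' @param negatives,positives At least 2 values per group.
#' @return The Z-factor, or `NA` if the means coincide.
#' @examples
#' # mu_N 1.0 sd_N 0.05, mu_P 0.1 sd_P 0.05 -> 1 - 0.3/0.9
#' @export
z_factor <- function(negatives, positives) {
  negatives <- negatives[is.finite(negatives)]
  positives <- positives[is.finite(positives)]
  if (length(negatives) < 2 || length(positives) < 2) {
    stop("need at least 2 values in each group")
  }
  denom <- abs(mean(positives) - mean(negatives))
  if (denom == 0) {
    warning("identical group means: Z-factor undefined")
    return(NA_real_)
  }
  1 - 3 * (stats::sd(positives) + stats::sd(negatives)) / denom
}

#' Quality-control thresholds
#'
#' @param cv_max Maximum coefficient of variation of the DMSO negatives.
#' @param z_min_plate Minimum Z-factor per plate.
#' @param z_min_set Minimum mean Z-factor across plates of a screening
#'   set.
#' @param pc_ratio_min Minimum NC:PC intensity ratio for a positive
#'   control to count as effective (cell line sensitive to it).
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(cv_max = 0.18, z_min_plate = 0.3,
                          z_min_set = 0.4, pc_ratio_min = 4) {
  list(cv_max = cv_max, z_min_plate = z_min_plate, z_min_set = z_min_set,
       pc_ratio_min = pc_ratio_min)
}

#' Plate-level quality control
#'
#' Applies the control-based pass rules to one plate of raw intensities:
#' the CV of the DMSO negatives must not exceed `cv_max`; for each
#' positive-control class to which the cell line is sensitive
#' (mean(NC)/mean(PC) >= `pc_ratio_min`) a Z-factor against the DMSO
#' negatives is computed and must reach `z_min_plate` — sensitivity to
#' both classes requires passing both; if the cell line is insensitive to
#' both positive controls, the Z-factor is computed against the blank
#' wells instead.
#'
#' @param wells Well table of a single plate (columns `well_role`,
#'   `intensity`); must contain the full control census.
#' @param thresholds A [qc_thresholds()] list.
#' @return Object of class `qc_report`: `plate_id`, `cv`, `z_factors`
#'   (named by control class used), `controls_used`, `pass`, `reasons`.
#' @export
qc_plate <- function(wells, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(wells),
            all(c("well_role", "intensity") %in% names(wells)))
  if ("plate_id" %in% names(wells) &&
      length(unique(wells$plate_id)) > 1) {
    stop("qc_plate expects wells of a single plate")
  }
  for (cls in c("untreated", "dmso", "blank", "pos1", "pos2")) {
    if (!any(wells$well_role == cls)) {
      stop("missing control class: ", cls)
    }
  }
  neg <- wells$intensity[wells$well_role == "dmso"]
  blank <- wells$intensity[wells$well_role == "blank"]
  cv <- coefficient_of_variation(neg)

  z <- c(); used <- character()
  for (cls in c("pos1", "pos2")) {
    pc <- wells$intensity[wells$well_role == cls]
    if (mean(neg) / mean(pc) >= thresholds$pc_ratio_min) {
      z[cls] <- z_factor(neg, pc)
      used <- c(used, cls)
    }
  }
  if (length(used) == 0) {
    z["blank"] <- z_factor(neg, blank)
    used <- "blank"
  }

  reasons <- character()
  if (!is.finite(cv) || cv > thresholds$cv_max) reasons <- c(reasons, "CV")
  bad <- !is.finite(z) | z < thresholds$z_min_plate
  if (any(bad)) {
    reasons <- c(reasons, paste0("Z-factor (", names(z)[bad], ")"))
  }
  structure(
    list(plate_id = if ("plate_id" %in% names(wells))
           wells$plate_id[1] else NA_character_,
         cv = cv, z_factors = z, controls_used = used,
         pass = length(reasons) == 0, reasons = reasons),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC %s: CV %.3f; Z [%s]; %s\n", x$plate_id, x$cv,
              paste(names(x$z_factors), round(x$z_factors, 3),
                    collapse = ", "),
              if (x$pass) "PASS" else
                paste("FAIL:", paste(x$reasons, collapse = "; "))))
  invisible(x)
}

#' Screening-set quality control
#'
#' Runs [qc_plate()] on every plate of a well table and adds the
#' set-level rule: the mean of all computed Z-factors across plates must
#' reach `z_min_set`, otherwise the whole set is flagged.
#'
#' @param wells Well table covering one or more plates (column
#'   `plate_id`).
#' @param thresholds A [qc_thresholds()] list.
#' @return Tibble with one row per plate (`plate_id`, `cv`, `z_min` — the
#'   smallest computed Z-factor, `controls_used`, `pass`, `reasons`), with
#'   attributes `mean_z` and `set_pass`.
#' @export
qc_screen <- function(wells, thresholds = qc_thresholds()) {
  ids <- unique(wells$plate_id)
  reports <- lapply(ids, function(id) {
    qc_plate(wells[wells$plate_id == id, ], thresholds)
  })
  tab <- tibble::tibble(
    plate_id = ids,
    cv = vapply(reports, function(r) r$cv, numeric(1)),
    z_min = vapply(reports, function(r) {
      if (all(is.na(r$z_factors))) NA_real_ else min(r$z_factors,
                                                     na.rm = TRUE)
    }, numeric(1)),
    controls_used = vapply(reports, function(r) {
      paste(r$controls_used, collapse = ",")
    }, character(1)),
    pass = vapply(reports, function(r) r$pass, logical(1)),
    reasons = vapply(reports, function(r) {
      paste(r$reasons, collapse = "; ")
    }, character(1)))
  all_z <- unlist(lapply(reports, function(r) r$z_factors))
  mean_z <- mean(all_z, na.rm = TRUE)
  attr(tab, "mean_z") <- mean_z
  attr(tab, "set_pass") <- is.finite(mean_z) &&
    mean_z >= thresholds$z_min_set
  tab
}

#' Normalize a well table plate-by-plate
#'
#' Adds a `viability` column to a raw well table, normalizing each plate
#' by its own blank and DMSO negative-control means.
#'
#' @param wells Raw well table (columns `plate_id`, `well_role`,
#'   `intensity`).
#' @return The well table with a `viability` column.
#' @export
normalize_wells <- function(wells) {
  dplyr::mutate(
    dplyr::group_by(wells, .data$plate_id),
    viability = normalize_viability(
      .data$intensity,
      mean(.data$intensity[.data$well_role == "blank"]),
      mean(.data$intensity[.data$well_role == "dmso"]))) |>
    dplyr::ungroup()
}
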