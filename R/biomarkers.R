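#' Build a response matrix for biomarker discovery
#'
#' Reduces per-tuple synergy metrics to one value per cell line and
#' combination for each response metric: responses are first averaged
#' across replicates within each anchor concentration, then the larger of
#' the two anchor-concentration delta IC50 and delta Emax values and the
#' smaller of the two combination Emax values are taken (capturing the
#' largest combination effect); the library IC50 is averaged. Tuples with
#' a single evaluated anchor concentration contribute their value
#' directly.
#'
#' @param tuples Per-tuple metrics from [score_screen()] (`$tuples`).
#' @param context Optional character vector of cell lines to restrict to
#'   (a molecular context); fewer than 8 lines triggers a warning.
#' @return Wide tibble: `cell_line` plus one column per
#'   `<anchor>+<library>::<metric>` with metrics `library_ic50`,
#'   `combo_emax`, `delta_ic50`, `delta_emax`.
#' @export
build_response_matrix <- function(tuples, context = NULL) {
  ev <- tuples[!tuples$excluded, ]
  if (!is.null(context)) ev <- ev[ev$cell_line %in% context, ]
  if (length(unique(ev$cell_line)) < 8) {
    warning("context has fewer than 8 cell lines; ",
            "associations will be underpowered")
  }
  # average replicate plates within anchor concentration first
  per_conc <- dplyr::summarise(
    dplyr::group_by(ev, .data$cell_line, .data$anchor_drug,
                    .data$library_drug, .data$anchor_conc_level),
    library_ic50 = mean(.data$library_ic50_log2),
    combo_emax = mean(.data$combo_emax),
    delta_ic50 = mean(.data$delta_ic50),
    delta_emax = mean(.data$delta_emax),
    .groups = "drop")
  red <- dplyr::summarise(
    dplyr::group_by(per_conc, .data$cell_line, .data$anchor_drug,
                    .data$library_drug),
    library_ic50 = mean(.data$library_ic50),
    combo_emax = min(.data$combo_emax),
    delta_ic50 = max(.data$delta_ic50),
    delta_emax = max(.data$delta_emax),
    .groups = "drop")
  long <- tidyr::pivot_longer(
    dplyr::mutate(red, combination = paste0(.data$anchor_drug, "+",
                                            .data$library_drug),
                  anchor_drug = NULL, library_drug = NULL),
    cols = c("library_ic50", "combo_emax", "delta_ic50", "delta_emax"),
    names_to = "metric", values_to = "value")
  wide <- tidyr::pivot_wider(
    dplyr::transmute(long, .data$cell_line,
                     column = paste0(.data$combination, "::",
                                     .data$metric),
                     .data$value),
    names_from = "column", values_from = "value")
  attr(wide, "context") <- context
  wide
}

#' Binarize gene expression within a molecular context
#'
#' z-scores each gene across the supplied cell lines (context-restricted
#' mean and sample standard deviation) and emits two binary features per
#' gene: `<gene>_up` where z >= 2 and `<gene>_down` where z <= -2.
#' Zero-variance genes yield no features; features with no positive cell
#' line are dropped.
#'
#' @param expression Numeric matrix, cell lines (rows) x genes (columns),
#'   with rownames.
#' @param context Optional cell-line subset defining the context; at least
#'   8 lines required.
#' @param z_cut |z| threshold (default 2).
#' @return Binary matrix, cell lines x features.
#' @export
binarize_expression <- function(expression, context = NULL, z_cut = 2) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  if (!is.null(context)) expression <- expression[context, , drop = FALSE]
  if (nrow(expression) < 8) {
    stop("expression binarization needs at least 8 cell lines in context")
  }
  cols <- list()
  for (g in colnames(expression)) {
    x <- expression[, g]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) next
    z <- (x - mean(x)) / s
    up <- as.integer(z >= z_cut)
    dn <- as.integer(z <= -z_cut)
    if (sum(up) > 0) cols[[paste0(g, "_up")]] <- up
    if (sum(dn) > 0) cols[[paste0(g, "_down")]] <- dn
  }
  if (length(cols) == 0) {
    m <- matrix(integer(), nrow = nrow(expression), ncol = 0,
                dimnames = list(rownames(expression), NULL))
    return(m)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(expression)
  m
}

#' ANOVA association between a binary feature and a response
#'
#' Fixed-effects ANOVA of a continuous response on a binary molecular
#' feature, optionally adjusted for an additive categorical covariate
#' (e.g. tissue in a pan-tissue analysis); the reported p-value is for
#' the feature term with the covariate fitted first. Effect sizes are the
#' two Glass deltas: the absolute group mean difference divided by the
#' sample standard deviation of the feature-positive and feature-negative
#' populations respectively (infinite when a group has zero variance).
#' For a two-group one-way design the p-value coincides with the
#' pooled-variance two-sided t-test (F = t^2).
#'
#' @param response Numeric response vector.
#' @param feature Binary (0/1) feature vector, same length.
#' @param covariate Optional factor covariate.
#' @param min_group Minimum non-missing responses per feature level
#'   (default 3); smaller groups yield a skipped association (NA p-value
#'   with a reason).
#' @return One-row tibble (`n_pos`, `n_neg`, `mean_diff`,
#'   `glass_delta_pos`, `glass_delta_neg`, `p_value`, `fdr`,
#'   `significant`, `reason`); `fdr` and `significant` are filled by
#'   [run_biomarker_scan()].
#' @export
anova_association <- function(response, feature, covariate = NULL,
                              min_group = 3) {
  stopifnot(length(response) == length(feature),
            all(feature %in% c(0, 1, NA)))
  keep <- is.finite(response) & !is.na(feature)
  if (!is.null(covariate)) keep <- keep & !is.na(covariate)
  y <- response[keep]; f <- feature[keep]
  cv <- if (is.null(covariate)) NULL else factor(covariate[keep])
  n_pos <- sum(f == 1); n_neg <- sum(f == 0)
  skip <- function(why) {
    tibble::tibble(n_pos = n_pos, n_neg = n_neg, mean_diff = NA_real_,
                   glass_delta_pos = NA_real_, glass_delta_neg = NA_real_,
                   p_value = NA_real_, fdr = NA_real_, significant = NA,
                   reason = why)
  }
  if (n_pos < min_group || n_neg < min_group) {
    return(skip(sprintf("group size < %d", min_group)))
  }
  mp <- mean(y[f == 1]); mn <- mean(y[f == 0])
  sp <- stats::sd(y[f == 1]); sn <- stats::sd(y[f == 0])
  diff <- mp - mn
  gdp <- if (sp == 0) Inf else abs(diff) / sp
  gdn <- if (sn == 0) Inf else abs(diff) / sn

  ff <- factor(f, levels = c(0, 1))
  fit <- if (is.null(cv) || length(unique(cv)) < 2) {
    stats::lm(y ~ ff)
  } else {
    stats::lm(y ~ cv + ff)
  }
  at <- stats::anova(fit)
  p <- at["ff", "Pr(>F)"]
  tibble::tibble(n_pos = n_pos, n_neg = n_neg, mean_diff = diff,
                 glass_delta_pos = gdp, glass_delta_neg = gdn,
                 p_value = p, fdr = NA_real_, significant = NA,
                 reason = NA_character_)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; a thin validated
#' wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NAs carried
#'   through).
#' @return Adjusted values, monotone in rank and <= 1.
#' @export
bh_fdr <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) for X hypergeometric: the probability of at least `k`
#' successes when drawing `n` items from a universe of `N` containing `K`
#' successes. Used to test synergy enrichment within baskets of
#' combinations.
#'
#' @param k Successes in the selection.
#' @param K Successes in the universe.
#' @param n Selection size.
#' @param N Universe size.
#' @return Enrichment p-value.
#' @examples
#' hypergeometric_enrichment(2, 2, 2, 4)  # 1/6
#' @export
hypergeometric_enrichment <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n))) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Scan all feature-response pairs for biomarker associations
#'
#' Runs [anova_association()] for every (feature, response column) pair
#' within each molecular context, adjusts p-values by Benjamini-Hochberg
#' within the chosen family (by default each (context, response metric)
#' pair; optionally per context or globally), and flags associations that
#' satisfy all of: p <= `p_max`, FDR <= `fdr_max`, and both Glass deltas
#' >= `glass_min`.
#'
#' @param responses Wide response tibble from [build_response_matrix()]
#'   (column `cell_line` plus `<combination>::<metric>` columns), or a
#'   numeric matrix with cell-line rownames.
#' @param features Binary matrix, cell lines x features (rownames =
#'   cell lines).
#' @param contexts Named list of cell-line subsets (default: one context
#'   `"all"` containing every shared cell line).
#' @param tissue Optional named character vector (cell line -> tissue);
#'   contexts spanning more than one tissue are adjusted for tissue as an
#'   additive covariate.
#' @param p_max,fdr_max,glass_min Significance thresholds.
#' @param fdr_family FDR family: `"context_metric"`, `"context"` or
#'   `"global"`.
#' @param min_group Minimum feature-level group size.
#' @return Tibble of associations sorted by p-value: `context`, `feature`,
#'   `response`, `metric`, association columns, `fdr`, `significant`.
#' @export
run_biomarker_scan <- function(responses, features, contexts = NULL,
                               tissue = NULL, p_max = 0.001,
                               fdr_max = 0.05, glass_min = 1,
                               fdr_family = c("context_metric", "context",
                                              "global"),
                               min_group = 3) {
  fdr_family <- match.arg(fdr_family)
  if (is.data.frame(responses)) {
    stopifnot("cell_line" %in% names(responses))
    rm <- as.matrix(responses[, setdiff(names(responses), "cell_line"),
                              drop = FALSE])
    rownames(rm) <- responses$cell_line
  } else {
    rm <- responses
  }
  stopifnot(!is.null(rownames(rm)), !is.null(rownames(features)))
  shared <- intersect(rownames(rm), rownames(features))
  orphans <- c(setdiff(rownames(rm), rownames(features)),
               setdiff(rownames(features), rownames(rm)))
  if (length(shared) == 0) {
    stop("no shared cell lines; orphans: ",
         paste(orphans, collapse = ", "))
  }
  if (is.null(contexts)) contexts <- list(all = shared)
  if (ncol(features) == 0 || ncol(rm) == 0) {
    return(tibble::tibble(context = character(), feature = character(),
                          response = character(), metric = character()))
  }

  out <- list()
  for (ctx in names(contexts)) {
    lines <- intersect(contexts[[ctx]], shared)
    cv <- NULL
    if (!is.null(tissue)) {
      tt <- tissue[lines]
      if (length(unique(tt)) > 1) cv <- tt
    }
    for (rc in colnames(rm)) {
      y <- rm[lines, rc]
      metric <- if (grepl("::", rc, fixed = TRUE)) {
        sub("^.*::", "", rc)
      } else {
        rc
      }
      for (fc in colnames(features)) {
        a <- anova_association(y, features[lines, fc], covariate = cv,
                               min_group = min_group)
        a$context <- ctx; a$feature <- fc; a$response <- rc
        a$metric <- metric
        out[[length(out) + 1]] <- a
      }
    }
  }
  res <- dplyr::bind_rows(out)
  fam <- switch(fdr_family,
                context_metric = paste(res$context, res$metric),
                context = res$context,
                global = rep("all", nrow(res)))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    res$fdr[idx] <- bh_fdr(res$p_value[idx])
  }
  res$significant <- !is.na(res$p_value) & res$p_value <= p_max &
    res$fdr <= fdr_max & res$glass_delta_pos >= glass_min &
    res$glass_delta_neg >= glass_min
  res <- res[order(res$p_value), ]
  cols <- c("context", "feature", "response", "metric", "n_pos", "n_neg",
            "mean_diff", "glass_delta_pos", "glass_delta_neg", "p_value",
            "fdr", "significant", "reason")
  res[, cols]
}
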