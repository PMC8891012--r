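#' Two-parameter sigmoid viability curve
#'
#' Viability as a function of standardized log2 concentration `x`:
#' `upper / (1 + exp((x - x_mid) / scale))`. The curve is strictly
#' decreasing, approaches `upper` at low dose and 0 at high dose, and
#' equals `upper / 2` at `x = x_mid` — so on this parameterization the
#' half-maximal concentration (IC50, measured between zero and the upper
#' asymptote) is `x_mid` itself.
#'
#' @param x Standardized log2 concentration(s).
#' @param x_mid Curve position: log2 concentration of the half-point.
#' @param scale Positive scale (inverse steepness); a Hill slope of h in
#'   log2 dose corresponds to `scale = 1 / (h * log(2))`.
#' @param upper Upper asymptote in (0, 1]: 1 for monotherapy, the anchor
#'   viability for anchor-capped combination curves.
#' @return Viability value(s).
#' @examples
#' sigmoid_viability(4, x_mid = 4, scale = 1, upper = 0.8)  # 0.4
#' @export
sigmoid_viability <- function(x, x_mid, scale, upper = 1) {
  stopifnot(all(scale > 0))
  upper / (1 + exp((x - x_mid) / scale))
}

new_curve_fit <- function(x_mid, scale, upper, doses, viabilities,
                          converged, rmse_max, free = c("x_mid", "scale"),
                          insensitive = FALSE) {
  pred <- sigmoid_viability(doses, x_mid, scale, upper)
  rmse <- sqrt(mean((viabilities - pred)^2))
  structure(
    list(x_mid = x_mid, scale = scale, upper = upper,
         ic50_log2 = x_mid,
         emax = sigmoid_viability(max(doses), x_mid, scale, upper),
         rmse = rmse, valid = isTRUE(converged) && rmse <= rmse_max,
         converged = converged, insensitive = insensitive,
         n_points = length(doses), doses = doses,
         viabilities = viabilities, free = free),
    class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid fit: x_mid %.3f, scale %.3f, upper %.3f | Emax %.3f, RMSE %.4f, %s\n",
    x$x_mid, x$scale, x$upper, x$emax, x$rmse,
    if (x$valid) "valid" else "invalid"))
  invisible(x)
}

#' @export
predict.curve_fit <- function(object, x = object$doses, ...) {
  sigmoid_viability(x, object$x_mid, object$scale, object$upper)
}

# residual weights for proportional-noise readouts
fit_weights <- function(viab, weighting) {
  if (weighting == "none") return(NULL)
  1 / pmax(viab, 0.1)^2
}

# bounded least squares with fixed multi-starts (deterministic)
ls_sigmoid <- function(doses, viab, upper, starts, lower, upper_b,
                       fixed_scale = NULL, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(viab))
  obj <- if (is.null(fixed_scale)) {
    function(p) {
      sum(weights *
            (sigmoid_viability(doses, p[1], p[2], upper) - viab)^2)
    }
  } else {
    function(p) {
      sum(weights *
            (sigmoid_viability(doses, p[1], fixed_scale, upper) - viab)^2)
    }
  }
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[k, ], obj, method = "L-BFGS-B", lower = lower,
                   upper = upper_b, control = list(factr = 1e2,
                                                   maxit = 500)),
      error = function(e) NULL)
    better <- !is.null(fit) &&
      (is.null(best) || fit$value < best$value - 1e-12 ||
         (fit$value <= best$value + 1e-12 &&
            fit$convergence < best$convergence))
    if (better) best <- fit
  }
  if (is.null(best)) return(NULL)
  # restart from the incumbent: an abnormal line-search exit at one start
  # must not mask a converged optimum
  polish <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper_b, control = list(factr = 1e2,
                                                 maxit = 500)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value + 1e-12) {
    polish$convergence <- min(polish$convergence, best$convergence)
    best <- polish
  }
  if (best$convergence != 0) {
    # an abnormal line-search exit at a point no perturbation improves is
    # convergence at machine precision, not a failure
    f0 <- best$value
    improvable <- FALSE
    for (j in seq_along(best$par)) {
      for (sgn in c(-1, 1)) {
        p <- best$par
        p[j] <- min(max(p[j] + sgn * 1e-5 * (1 + abs(p[j])),
                        lower[min(j, length(lower))]),
                    upper_b[min(j, length(upper_b))])
        if (obj(p) < f0 - 1e-10 * (1 + f0)) improvable <- TRUE
      }
    }
    if (!improvable) best$convergence <- 0
  }
  best$par <- unname(best$par)
  best
}

#' Fit a library (monotherapy) dose-response curve
#'
#' Least-squares fit of the two-parameter sigmoid to replicate-averaged
#' viabilities with the upper asymptote fixed at 1. The optimizer is
#' bounded (`scale` in \[0.05, 10\], `x_mid` in \[-10, 20\]) and started
#' from three fixed positions so fits are deterministic. `x_mid` may fall
#' outside the tested range (extrapolated IC50) and is reported as-is;
#' downstream synergy gating handles censoring. A fit is `valid` when the
#' optimizer converged and RMSE <= `rmse_max`.
#'
#' @param doses Standardized log2 concentrations (7-point design; at least
#'   5 non-missing points required).
#' @param viabilities Replicate-averaged normalized viabilities, same
#'   length as `doses`.
#' @param rmse_max RMSE validity threshold (default 0.2).
#' @param weighting `"relative"` (default) weights squared residuals by
#'   `1 / max(viability, 0.1)^2`, matching the proportional noise of
#'   luminescence viability readouts (the floor covers the additive
#'   background that dominates near zero viability); `"none"` is ordinary
#'   least squares. The reported RMSE is always unweighted.
#' @return A `curve_fit`: `x_mid` (= `ic50_log2`), `scale`, fixed `upper`,
#'   `emax` (fitted viability at the highest tested concentration),
#'   `rmse`, `valid`, and an `insensitive` flag when all observed
#'   viabilities exceed 0.9 (no half-point within range).
#' @examples
#' d <- library_doses()
#' fit_library(d, sigmoid_viability(d, x_mid = 4, scale = 1))
#' @export
fit_library <- function(doses, viabilities, rmse_max = 0.2,
                        weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  keep <- is.finite(doses) & is.finite(viabilities)
  doses <- doses[keep]; viabilities <- viabilities[keep]
  if (length(doses) < 5) {
    stop("at least 5 non-missing dose points are required")
  }
  w <- fit_weights(viabilities, weighting)
  starts <- cbind(x_mid = c(2, 5, 8), scale = c(1, 1, 1))
  best <- ls_sigmoid(doses, viabilities, upper = 1, starts = starts,
                     lower = c(-10, 0.05), upper_b = c(20, 10),
                     weights = w)
  if (is.null(best)) {
    return(new_curve_fit(NA_real_, NA_real_, 1, doses, viabilities,
                         converged = FALSE, rmse_max = rmse_max))
  }
  new_curve_fit(best$par[1], best$par[2], 1, doses, viabilities,
                converged = best$convergence == 0, rmse_max = rmse_max,
                insensitive = all(viabilities > 0.9))
}

#' Fit an anchor-capped combination dose-response curve
#'
#' Fits the combination dose response with the upper asymptote fixed at
#' the anchor viability `A` (the curve runs from `A` to 0, and its IC50 is
#' the 50% point between zero and `A`). Cell-line curve shape is taken
#' from the library fit: by default the scale is tied to the library
#' fit's scale and only `x_mid` is re-estimated, which stabilizes
#' single-replicate combination fits; `free_scale = TRUE` re-estimates
#' both parameters.
#'
#' @inheritParams fit_library
#' @param anchor_viability Anchor viability `A` in (0, 1].
#' @param library_fit A valid `curve_fit` of the library drug in the same
#'   cell line.
#' @param free_scale Re-estimate the scale instead of tying it to the
#'   library fit.
#' @return A `curve_fit` with `upper = anchor_viability`.
#' @export
fit_combination <- function(doses, viabilities, anchor_viability,
                            library_fit, free_scale = FALSE,
                            rmse_max = 0.2,
                            weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(library_fit, "curve_fit"),
            anchor_viability > 0, anchor_viability <= 1)
  if (!library_fit$valid) {
    stop("library fit must be valid to anchor a combination fit")
  }
  keep <- is.finite(doses) & is.finite(viabilities)
  doses <- doses[keep]; viabilities <- viabilities[keep]
  if (length(doses) < 5) {
    stop("at least 5 non-missing dose points are required")
  }
  w <- fit_weights(viabilities, weighting)
  if (free_scale) {
    starts <- cbind(x_mid = c(2, 5, 8),
                    scale = rep(library_fit$scale, 3))
    best <- ls_sigmoid(doses, viabilities, upper = anchor_viability,
                       starts = starts, lower = c(-10, 0.05),
                       upper_b = c(20, 10), weights = w)
    if (is.null(best)) {
      return(new_curve_fit(NA_real_, NA_real_, anchor_viability, doses,
                           viabilities, converged = FALSE,
                           rmse_max = rmse_max))
    }
    return(new_curve_fit(best$par[1], best$par[2], anchor_viability,
                         doses, viabilities,
                         converged = best$convergence == 0,
                         rmse_max = rmse_max))
  }
  starts <- cbind(x_mid = c(2, 5, 8))
  best <- ls_sigmoid(doses, viabilities, upper = anchor_viability,
                     starts = starts, lower = -10, upper_b = 20,
                     fixed_scale = library_fit$scale, weights = w)
  if (is.null(best)) {
    return(new_curve_fit(NA_real_, library_fit$scale, anchor_viability,
                         doses, viabilities, converged = FALSE,
                         rmse_max = rmse_max, free = "x_mid"))
  }
  new_curve_fit(best$par[1], library_fit$scale, anchor_viability, doses,
                viabilities, converged = best$convergence == 0,
                rmse_max = rmse_max, free = "x_mid")
}

#' Anchor viability from replicate anchor-only wells
#'
#' Arithmetic mean across the replicate anchor-only wells on a plate,
#' clipped to (0, 1]. Missing replicates are dropped with a warning when
#' fewer than 3 remain; if all are missing the tuple cannot be evaluated
#' and `NA` is returned.
#'
#' @param viabilities Normalized viabilities of the replicate wells
#'   (nominally 5).
#' @return Mean anchor viability in (0, 1], or `NA` if all missing.
#' @export
anchor_viability <- function(viabilities) {
  v <- viabilities[is.finite(viabilities)]
  if (length(v) == 0) {
    warning("all anchor replicates missing; tuple excluded")
    return(NA_real_)
  }
  if (length(v) < 3) {
    warning("anchor viability based on only ", length(v), " replicate(s)")
  }
  min(max(mean(v), 1e-6), 1)
}
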