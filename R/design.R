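#' Standardized library concentration series
#'
#' Library drugs are screened at seven concentrations spanning a 1,024-fold
#' range with a non-equidistant log2 design: four 4-fold steps followed by
#' two 2-fold steps, densest near the top of the range. Concentrations are
#' expressed on a standardized log2 scale on which the highest screened
#' concentration maps to 9.
#'
#' @param top Standardized log2 value of the highest concentration
#'   (default 9).
#' @return Numeric vector of 7 standardized log2 concentrations, increasing.
#' @examples
#' library_doses()
#' @export
library_doses <- function(top = 9) {
  top - rev(cumsum(c(0, 1, 1, 2, 2, 2, 2)))
}

#' Default per-plate control-well census
#'
#' Each screening plate carries negative controls (untreated wells and
#' DMSO-treated wells), medium-only blanks, and two cytotoxic positive
#' controls (e.g. staurosporine and MG-132).
#'
#' @return Named integer vector of well counts per control class.
#' @export
control_census <- function() {
  c(untreated = 6L, dmso = 126L, blank = 28L, pos1 = 20L, pos2 = 20L)
}

#' Define an anchored combination screen
#'
#' Describes the layout of a 2 x 7 anchored screen: each anchor drug is
#' tested at two fixed concentrations against the full 7-point dose
#' response of each library drug, on one plate per
#' (cell line, anchor, library) triple. Every plate carries the control
#' census, five replicates of each anchor concentration alone, four
#' replicates of the library dose response alone, and a single replicate
#' of the combination dose response at each anchor concentration.
#'
#' @param cell_lines Character vector of cell-line identifiers.
#' @param anchors Data frame with columns `drug`, `conc_low_log2`,
#'   `conc_high_log2` (standardized log2 scale; high > low).
#' @param libraries Data frame with columns `drug` and optionally
#'   `top_log2` (default 9); the 7-point series is derived with
#'   [library_doses()].
#' @param tissues Optional character vector of tissue labels, one per cell
#'   line (recycled if length 1).
#' @param census Named integer vector of control-well counts per plate.
#' @param n_rep Replicate counts per measurement class: anchor-only,
#'   library-only, combination.
#' @return An object of class `screen_design`.
#' @examples
#' design <- screen_design(
#'   cell_lines = c("CL1", "CL2"),
#'   anchors = data.frame(drug = "anchorA", conc_low_log2 = 5,
#'                        conc_high_log2 = 7),
#'   libraries = data.frame(drug = "libB")
#' )
#' design
#' @export
screen_design <- function(cell_lines, anchors, libraries, tissues = NULL,
                          census = control_census(),
                          n_rep = c(anchor = 5L, library = 4L,
                                    combination = 1L)) {
  stopifnot(is.character(cell_lines), length(cell_lines) >= 1)
  anchors <- tibble::as_tibble(anchors)
  libraries <- tibble::as_tibble(libraries)
  req <- c("drug", "conc_low_log2", "conc_high_log2")
  if (!all(req %in% names(anchors))) {
    stop("`anchors` must have columns: ", paste(req, collapse = ", "))
  }
  if (!"drug" %in% names(libraries)) stop("`libraries` must have a `drug` column")
  if (!"top_log2" %in% names(libraries)) libraries$top_log2 <- 9
  if (any(anchors$conc_high_log2 <= anchors$conc_low_log2)) {
    stop("each anchor must have conc_high_log2 > conc_low_log2")
  }
  need <- c("untreated", "dmso", "blank", "pos1", "pos2")
  if (!all(need %in% names(census))) {
    stop("census must name classes: ", paste(need, collapse = ", "))
  }
  if (is.null(tissues)) tissues <- rep("unspecified", length(cell_lines))
  if (length(tissues) == 1) tissues <- rep(tissues, length(cell_lines))
  stopifnot(length(tissues) == length(cell_lines))

  # invariant check: each derived series has steps (2,2,2,2,1,1) up to top
  for (top in unique(libraries$top_log2)) {
    d <- library_doses(top)
    stopifnot(length(d) == 7, all(diff(d) == c(2, 2, 2, 2, 1, 1)),
              d[7] == top)
  }

  structure(
    list(cell_lines = cell_lines,
         tissues = stats::setNames(tissues, cell_lines),
         anchors = anchors, libraries = libraries,
         census = census, n_rep = n_rep),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Anchored combination screen design\n")
  cat(sprintf("  %d cell lines (%s)\n", length(x$cell_lines),
              paste(unique(x$tissues), collapse = ", ")))
  cat(sprintf("  %d anchors x %d library drugs; %d plates\n",
              nrow(x$anchors), nrow(x$libraries),
              length(x$cell_lines) * nrow(x$anchors) * nrow(x$libraries)))
  cat(sprintf("  controls/plate: %s\n",
              paste(names(x$census), x$census, collapse = ", ")))
  invisible(x)
}

# all plates of a design, in deterministic order
design_plates <- function(design) {
  g <- expand.grid(library_drug = design$libraries$drug,
                   anchor_drug = design$anchors$drug,
                   cell_line = design$cell_lines,
                   stringsAsFactors = FALSE)
  g <- g[, c("cell_line", "anchor_drug", "library_drug")]
  g$plate_id <- sprintf("P%04d", seq_len(nrow(g)))
  tibble::as_tibble(g)
}
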