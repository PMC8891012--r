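lib_fit_from <- function(x_mid, scale = 1) {
  d <- library_doses()
  fit_library(d, sigmoid_viability(d, x_mid, scale))
}

combo_fit_from <- function(x_mid, A, library_fit, scale = library_fit$scale) {
  d <- library_doses()
  fit_combination(d, sigmoid_viability(d, x_mid, scale, upper = A), A,
                  library_fit)
}

test_that("Bliss curve is the anchor-scaled library curve with unchanged IC50", {
  lib <- lib_fit_from(4)
  for (A in c(0.3, 0.8, 1)) {
    bl <- bliss_expected(A, lib)
    expect_equal(bl$ic50_log2, lib$x_mid)
    expect_equal(bl$emax, A * lib$emax)
    x <- seq(-1, 9, 0.5)
    expect_equal(bl$predict(x), A * predict(lib, x))
    # the Bliss curve crosses A/2 exactly at the library x_mid
    expect_equal(bl$predict(lib$x_mid), A / 2, tolerance = 1e-9)
  }
})

test_that("deltas follow their definitions and additive tuples are not called", {
  lib <- lib_fit_from(6)
  A <- 0.8
  addi <- synergy_metrics(A, lib, combo_fit_from(6, A, lib))
  expect_equal(addi$delta_ic50, 0, tolerance = 1e-3)
  expect_equal(addi$delta_emax, 0, tolerance = 1e-3)
  expect_false(addi$synergy)
  expect_equal(addi$delta_ic50, addi$bliss_ic50_log2 - addi$combo_ic50_log2)
  expect_equal(addi$delta_emax, addi$bliss_emax - addi$combo_emax)

  # a potency shift past the 8-fold (3 log2) gate triggers a call
  syn <- synergy_metrics(A, lib, combo_fit_from(2.5, A, lib))
  expect_equal(syn$delta_ic50, 3.5, tolerance = 1e-3)
  expect_true(syn$qualifies)
  expect_true(syn$synergy)
})

test_that("out-of-range combination IC50 disqualifies efficacy synergy", {
  lib <- lib_fit_from(16)  # essentially inactive library drug
  A <- 0.9
  met <- synergy_metrics(A, lib, combo_fit_from(10.2, A, lib))
  expect_gte(met$delta_emax, 0.2)
  expect_false(met$qualifies)
  expect_false(met$synergy)
  met2 <- synergy_metrics(A, lib, combo_fit_from(7, A, lib))
  expect_true(met2$qualifies)
  expect_true(met2$synergy)
})

test_that("delta IC50 is invariant to shifting the concentration scale", {
  d <- library_doses()
  ylib <- sigmoid_viability(d, 5, 1)
  ycmb <- sigmoid_viability(d, 3, 1, upper = 0.7)
  m1 <- synergy_metrics(0.7, fit_library(d, ylib),
                        fit_combination(d, ycmb, 0.7,
                                        fit_library(d, ylib)))
  off <- 3.2  # e.g. molar-to-standardized relabelling
  lib2 <- fit_library(d + off, ylib)
  m2 <- synergy_metrics(0.7, lib2,
                        fit_combination(d + off, ycmb, 0.7, lib2))
  expect_equal(m1$delta_ic50, m2$delta_ic50, tolerance = 1e-6)
})

test_that("replicate calls are majority-voted and anchors are OR-aggregated", {
  expect_true(aggregate_replicates(c(TRUE, FALSE)))
  expect_false(aggregate_replicates(c(FALSE, FALSE, TRUE)))
  expect_true(aggregate_replicates(TRUE))
  expect_error(aggregate_replicates(logical(0)), "no replicate")

  expect_true(aggregate_anchors(TRUE, FALSE))
  expect_false(aggregate_anchors(FALSE, FALSE))
  expect_true(aggregate_anchors(TRUE, TRUE))
  expect_equal(aggregate_anchors(TRUE, FALSE),
               aggregate_anchors(FALSE, TRUE))
  expect_true(aggregate_anchors(NA, TRUE))
  expect_error(aggregate_anchors(NA, NA), "no anchor")
})

test_that("reproducibility scores match hand-computed confusion counts", {
  keys <- tibble::tibble(cell_line = sprintf("CL%d", 1:5),
                         anchor_drug = "a", library_drug = "l")
  s1 <- dplyr::mutate(keys, synergy = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                      delta_emax = c(0.5, 0.4, 0.3, 0.25, 0.05))
  s2 <- dplyr::mutate(keys, synergy = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                      delta_emax = c(0.52, 0.38, 0.33, 0.18, 0.22))
  r <- reproducibility(s1, s2)
  expect_equal(c(r$tp, r$fp, r$fn), c(3, 1, 1))
  expect_equal(r$f_score, 3 / (3 + 0.5 * 2))
  expect_equal(r$recall, 0.75)
  expect_equal(r$precision, 0.75)
  expect_equal(r$cor_delta_emax, cor(s1$delta_emax, s2$delta_emax))

  ident <- reproducibility(s1, s1)
  expect_equal(c(ident$f_score, ident$recall, ident$precision),
               c(1, 1, 1))
  allneg <- dplyr::mutate(s2, synergy = FALSE)
  expect_equal(reproducibility(s1, allneg)$recall, 0)
  expect_error(reproducibility(s1, dplyr::mutate(keys,
                                                 cell_line = "other",
                                                 synergy = TRUE)),
               "no keys")
})

test_that("synergy rates count evaluable pairs and support rate filters", {
  calls <- tibble::tibble(
    tissue = rep(c("breast", "colon"), c(10, 5)),
    synergy = c(rep(c(TRUE, FALSE), c(2, 8)), rep(c(TRUE, FALSE), c(2, 3))))
  r <- synergy_rate(calls, by = "tissue")
  expect_equal(r$rate[r$tissue == "breast"], 0.2)
  expect_equal(r$rate[r$tissue == "colon"], 0.4)
  expect_equal(nrow(synergy_rate(calls, by = "tissue", min_rate = 0.3)), 1)
})

test_that("scored screens recover planted synergy and flag dual-anchor calls", {
  design <- small_design(n_cl = 2, n_libs = 2)
  syn <- tibble::tibble(cell_line = "CL01", anchor_drug = "anc1",
                        library_drug = "lib1", delta_pot = 4,
                        delta_eff = 0)
  truth <- manual_truth(design, x_mid = 6, scale = 1, synergy = syn,
                        viability_sd = 0.03, intensity_sd = 50)
  sim <- simulate_screen(design, truth, seed = 11)
  sc <- score_screen(sim$wells, qc = qc_screen(sim$wells))
  pr <- sc$pairs
  hit <- pr[pr$cell_line == "CL01" & pr$library_drug == "lib1", ]
  expect_true(hit$synergy)
  expect_true(hit$dual_anchor)
  others <- pr[!(pr$cell_line == "CL01" & pr$library_drug == "lib1"), ]
  expect_false(any(others$synergy))
})
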