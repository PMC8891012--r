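test_that("library dose series follows the 4-fold/2-fold design ending at 9", {
  d <- library_doses()
  expect_length(d, 7)
  expect_equal(diff(d), c(2, 2, 2, 2, 1, 1))
  expect_equal(max(d), 9)
  expect_equal(library_doses(top = 5), library_doses() - 4)
})

test_that("screen design validates anchors and census", {
  expect_error(screen_design("CL1",
                             anchors = data.frame(drug = "a",
                                                  conc_low_log2 = 7,
                                                  conc_high_log2 = 5),
                             libraries = data.frame(drug = "l")),
               "high")
  d <- small_design()
  expect_equal(unname(d$census["dmso"]), 126L)
  expect_equal(sum(d$census), 200L)
})

test_that("simulated plates carry the exact design census and well counts", {
  design <- small_design(n_cl = 2, n_libs = 2)
  sim <- simulate_screen(design, manual_truth(design), seed = 5)
  counts <- table(sim$wells$plate_id, sim$wells$well_role)
  expect_true(all(counts[, "dmso"] == 126))
  expect_true(all(counts[, "untreated"] == 6))
  expect_true(all(counts[, "blank"] == 28))
  expect_true(all(counts[, "pos1"] == 20))
  expect_true(all(counts[, "pos2"] == 20))
  expect_true(all(counts[, "anchor"] == 2 * 5))       # 5 reps x 2 concs
  expect_true(all(counts[, "library"] == 4 * 7))      # 4 reps x 7 doses
  expect_true(all(counts[, "combination"] == 2 * 7))  # 1 rep x 2 concs
})

test_that("identical seeds give byte-identical screens", {
  design <- small_design()
  truth <- random_ground_truth(design, seed = 9)
  s1 <- simulate_screen(design, truth, seed = 4)
  s2 <- simulate_screen(design, truth, seed = 4)
  expect_identical(s1$wells, s2$wells)
  s3 <- simulate_screen(design, truth, seed = 5)
  expect_false(identical(s1$wells$intensity, s3$wells$intensity))
})

test_that("noiseless inert anchor reproduces the library sigmoid exactly", {
  design <- small_design(n_cl = 1, n_libs = 1)
  truth <- manual_truth(design, x_mid = 4, scale = 1, a_low = 1,
                        a_high = 1)
  sim <- simulate_screen(design, truth, seed = 1)
  w <- normalize_wells(sim$wells)
  combo <- w[w$well_role == "combination" & w$anchor_conc_log2 == 5, ]
  combo <- combo[order(combo$library_conc_log2), ]
  expect_equal(combo$viability,
               sigmoid_viability(combo$library_conc_log2, 4, 1),
               tolerance = 1e-9)
})

test_that("Bliss product gives combination viability A x library Emax at top dose", {
  # library with true Emax 0.5 (x_mid at the top dose), anchor at 0.8
  design <- small_design(n_cl = 1, n_libs = 1)
  truth <- manual_truth(design, x_mid = 9, scale = 1, a_low = 0.8,
                        a_high = 0.8)
  sim <- simulate_screen(design, truth, seed = 1)
  w <- normalize_wells(sim$wells)
  top <- w[w$well_role == "combination" & w$library_conc_log2 == 9 &
             w$anchor_conc_log2 == 5, ]
  expect_equal(top$viability, 0.40, tolerance = 1e-9)
})

test_that("injected shifts are echoed as achieved true deltas", {
  design <- small_design(n_cl = 1, n_libs = 2)
  syn_pot <- tibble::tibble(cell_line = "CL01", anchor_drug = "anc1",
                            library_drug = "lib1", delta_pot = 4,
                            delta_eff = 0)
  pot <- manual_truth(design, x_mid = 5, scale = 1,
                      synergy = syn_pot)$combinations
  expect_equal(pot$delta_ic50_true[pot$library_drug == "lib1"], rep(4, 2))

  # efficacy shifts need a weak library background to be expressible
  syn_eff <- tibble::tibble(cell_line = "CL01", anchor_drug = "anc1",
                            library_drug = "lib2", delta_pot = 0,
                            delta_eff = 0.1)
  eff <- manual_truth(design, x_mid = 12, scale = 1,
                      synergy = syn_eff)$combinations
  expect_equal(eff$delta_emax_true[eff$library_drug == "lib2"],
               rep(0.1, 2), tolerance = 1e-9)
  # on a potent background the achievable efficacy gain is the Bliss Emax
  floor <- manual_truth(design, x_mid = 5, scale = 1,
                        synergy = syn_eff)$combinations
  fl <- floor[floor$library_drug == "lib2", ]
  expect_true(all(fl$delta_emax_true < 0.1))
  expect_equal(fl$delta_emax_true, fl$bliss_emax_true, tolerance = 1e-3)

  add <- manual_truth(design, x_mid = 5, scale = 1)$combinations
  expect_true(all(add$delta_ic50_true == 0))
  expect_true(all(add$delta_emax_true == 0))
})

test_that("ground truth mismatches name the missing key", {
  design <- small_design(n_cl = 2, n_libs = 1)
  truth <- manual_truth(design)
  bad <- truth
  bad$library_params <- bad$library_params[-1, ]
  expect_error(simulate_screen(design, bad, seed = 1),
               "missing library curve")
})

test_that("feature simulation plants testable associations and outliers", {
  planted <- tibble::tibble(feature = "mutX", combination = "a+b",
                            effect_size = 2, n_pos = 15)
  fs <- simulate_features(sprintf("CL%02d", 1:30), planted = planted,
                          n_background_features = 20, seed = 2,
                          expr_genes = 10, expr_outliers = 2)
  expect_equal(dim(fs$features), c(30, 21))
  expect_equal(sum(fs$features[, "mutX"]), 15)
  resp <- simulate_biomarker_responses(fs$features, planted, seed = 3)
  pos <- fs$features[, "mutX"] == 1
  expect_gt(mean(resp[pos, 1]) - mean(resp[!pos, 1]), 1)
  # planted expression outliers binarize past |z| = 2
  bin <- binarize_expression(fs$expression)
  out <- fs$truth$outliers
  for (j in seq_len(nrow(out))) {
    col <- paste0(out$gene[j], "_", out$direction[j])
    expect_true(col %in% colnames(bin))
    expect_equal(bin[out$cell_line[j], col], 1L)
  }
  expect_warning(
    simulate_features(sprintf("CL%02d", 1:10),
                      planted = tibble::tibble(feature = "f",
                                               combination = "c",
                                               effect_size = 1,
                                               n_pos = 1),
                      n_background_features = 0, seed = 1),
    "untestable")
})
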