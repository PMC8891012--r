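make_tuples <- function() {
  tibble::tibble(
    cell_line = rep(c("CL01", "CL02"), c(2, 1)),
    anchor_drug = "anc1", library_drug = "lib1",
    anchor_conc_level = c("low", "high", "low"),
    library_ic50_log2 = c(4, 4, 6),
    combo_emax = c(0.3, 0.2, 0.5),
    delta_ic50 = c(1.0, 2.5, 0.2),
    delta_emax = c(0.05, 0.15, 0.01),
    excluded = FALSE)
}

test_that("response matrix takes the extreme anchor value per pair", {
  rm_ <- suppressWarnings(build_response_matrix(make_tuples()))
  r1 <- rm_[rm_$cell_line == "CL01", ]
  expect_equal(r1[["anc1+lib1::delta_ic50"]], 2.5)  # larger of the two
  expect_equal(r1[["anc1+lib1::combo_emax"]], 0.2)  # smaller of the two
  expect_equal(r1[["anc1+lib1::delta_emax"]], 0.15)
  expect_equal(r1[["anc1+lib1::library_ic50"]], 4)
  # single-anchor tuple contributes its value directly
  r2 <- rm_[rm_$cell_line == "CL02", ]
  expect_equal(r2[["anc1+lib1::delta_ic50"]], 0.2)
  expect_warning(build_response_matrix(make_tuples()), "fewer than 8")
})

test_that("expression binarization emits up/down features at |z| >= 2", {
  cl <- sprintf("CL%02d", 1:10)
  e <- matrix(0, 10, 3, dimnames = list(cl, c("gA", "gB", "gC")))
  e[1, "gA"] <- 10               # z = 9/sqrt(10) = 2.85
  e[2, "gB"] <- -10
  # gC constant: no features
  b <- binarize_expression(e)
  expect_setequal(colnames(b), c("gA_up", "gB_down"))
  expect_equal(unname(b[, "gA_up"]), c(1L, rep(0L, 9)))
  expect_equal(unname(b[, "gB_down"]), c(0L, 1L, rep(0L, 8)))
  expect_error(binarize_expression(e[1:5, ]), "at least 8")
})

test_that("two-group ANOVA equals the pooled t-test and Glass deltas are per-group", {
  a <- anova_association(c(1, 2, 3, 5, 6, 7), c(1, 1, 1, 0, 0, 0))
  expect_equal(abs(a$mean_diff), 4)
  expect_equal(a$glass_delta_pos, 4)
  expect_equal(a$glass_delta_neg, 4)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    f <- rbinom(n, 1, 0.5)
    if (sum(f) < 3 || sum(1 - f) < 3) next
    y <- rnorm(n) + 0.8 * f
    a <- anova_association(y, f)
    tt <- t.test(y[f == 1], y[f == 0], var.equal = TRUE)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Glass deltas are invariant to shifting and rescaling responses", {
  set.seed(9)
  y <- rnorm(20, 5, 2); f <- rep(c(0, 1), 10)
  a <- anova_association(y, f)
  b <- anova_association(y + 17.3, f)
  d <- anova_association(y * 4.2, f)
  expect_equal(a$glass_delta_pos, b$glass_delta_pos)
  expect_equal(a$glass_delta_neg, b$glass_delta_neg)
  expect_equal(a$glass_delta_pos, d$glass_delta_pos, tolerance = 1e-12)
})

test_that("small groups are skipped with a reason, zero variance gives infinite delta", {
  a <- anova_association(1:10, c(1, rep(0, 9)))
  expect_true(is.na(a$p_value))
  expect_match(a$reason, "group size")
  b <- anova_association(c(2, 2, 2, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(b$glass_delta_pos, Inf)
})

test_that("covariate-adjusted ANOVA removes a tissue confound", {
  set.seed(10)
  tissue <- rep(c("breast", "colon"), each = 15)
  f <- c(rbinom(15, 1, 0.8), rbinom(15, 1, 0.2))  # feature tracks tissue
  y <- ifelse(tissue == "breast", 3, 0) + rnorm(30, 0, 0.7)
  raw <- anova_association(y, f)
  adj <- anova_association(y, f, covariate = tissue)
  expect_lt(raw$p_value, 0.01)   # confounded signal
  expect_gt(adj$p_value, 0.05)   # gone once tissue is modelled
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_lt(max(abs(bh_fdr(p) - oracle_bh(p))), 1e-12)
  }
})

test_that("hypergeometric enrichment matches coefficient-ratio enumeration", {
  expect_equal(hypergeometric_enrichment(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeometric_enrichment(0, 5, 3, 10), 1)
  expect_equal(hypergeometric_enrichment(3, 8, 3, 8), 1)  # K = N
  expect_error(hypergeometric_enrichment(5, 2, 3, 10), "inconsistent")
  enum <- function(k, K, n, N) {
    js <- k:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
  }
  set.seed(12)
  for (i in 1:30) {
    N <- sample(4:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_enrichment(k, K, n, N), enum(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("the scan flags planted biomarkers and is duplication-invariant", {
  cl <- sprintf("CL%02d", 1:30)
  planted <- tibble::tibble(feature = "mutX", combination = "a+l",
                            effect_size = 2, n_pos = 15)
  fs <- simulate_features(cl, planted, n_background_features = 30,
                          seed = 21)
  resp <- simulate_biomarker_responses(fs$features, planted, seed = 22)
  res <- run_biomarker_scan(resp, fs$features)
  expect_equal(res$feature[1], "mutX")
  expect_true(res$significant[1])

  dup <- cbind(fs$features, mutX_copy = fs$features[, "mutX"])
  res2 <- run_biomarker_scan(resp, dup)
  p <- res2$p_value[match(c("mutX", "mutX_copy"), res2$feature)]
  expect_equal(p[1], p[2])

  empty <- run_biomarker_scan(resp, fs$features[, 0, drop = FALSE])
  expect_equal(nrow(empty), 0)

  rownames(resp) <- paste0("X", rownames(resp))
  expect_error(run_biomarker_scan(resp, fs$features), "orphans")
})
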