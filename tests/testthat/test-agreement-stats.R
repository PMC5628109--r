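test_that("bundled risk tables have the published marginal totals", {
  tabs <- cac_example_tables()
  expect_named(tabs, c("ctac_rest_manual_vs_auto", "ctac_stress_manual_vs_auto",
                       "csct_vs_ctac_rest_manual", "csct_vs_ctac_rest_auto",
                       "csct_vs_ctac_stress_manual", "csct_vs_ctac_stress_auto"))
  expect_identical(rowSums(tabs$ctac_rest_manual_vs_auto),
                   c(17, 6, 18, 37, 50))
  expect_identical(rowSums(tabs$ctac_stress_manual_vs_auto),
                   c(20, 2, 24, 34, 48))
  for (nm in names(tabs)[3:6])
    expect_identical(rowSums(tabs[[nm]]), c(13, 6, 12, 35, 62))
  for (t in tabs) expect_identical(sum(t), 128L)
})

test_that("linearly weighted kappa reproduces the published worked examples", {
  tabs <- cac_example_tables()
  expected <- c(ctac_rest_manual_vs_auto = 0.85,
                ctac_stress_manual_vs_auto = 0.89,
                csct_vs_ctac_rest_manual = 0.82,
                csct_vs_ctac_rest_auto = 0.74,
                csct_vs_ctac_stress_manual = 0.79,
                csct_vs_ctac_stress_auto = 0.70)
  for (nm in names(expected)) {
    r <- weighted_kappa(tabs[[nm]])
    expect_equal(round(r$kappa, 2), unname(expected[nm]), info = nm)
    expect_true(r$kappa_ci95[1] <= r$kappa && r$kappa <= r$kappa_ci95[2])
  }
})

test_that("kappa hits its algebraic anchors", {
  expect_equal(weighted_kappa(diag(10, 5))$kappa, 1)
  expect_equal(weighted_kappa(matrix(c(5, 5, 5, 5), 2))$kappa, 0)
  # 2x2 degeneracy: linear, quadratic and unweighted kappa coincide
  m <- matrix(c(30, 5, 10, 25), 2)
  lin <- weighted_kappa(m, "linear")$kappa
  quad <- weighted_kappa(m, "quadratic")$kappa
  p <- m / sum(m)
  po <- sum(diag(p)); pe <- sum(rowSums(p) * colSums(p))
  expect_equal(lin, (po - pe) / (1 - pe))
  expect_equal(quad, lin)
  expect_error(weighted_kappa(matrix(c(10, 0, 0, 0), 2)), "undefined")
})

test_that("kappa depends on the ordinal ordering of categories", {
  m <- cac_example_tables()$ctac_rest_manual_vs_auto
  perm <- c(1, 3, 5, 2, 4)      # scramble the ordinal order
  expect_false(isTRUE(all.equal(weighted_kappa(m[perm, perm])$kappa,
                                weighted_kappa(m)$kappa)))
})

test_that("kappa of independent-margin tables is centred on zero", {
  set.seed(99)
  r <- c(0.1, 0.1, 0.25, 0.3, 0.25)
  s <- c(0.2, 0.1, 0.3, 0.2, 0.2)
  cellp <- as.vector(outer(r, s))
  n_draws <- 10000
  kappas <- vapply(seq_len(n_draws), function(i) {
    m <- matrix(rmultinom(1, 200, cellp), 5)
    weighted_kappa(m)$kappa
  }, numeric(1))
  expect_lt(abs(mean(kappas)), 4 * sd(kappas) / sqrt(n_draws))
})

test_that("accuracy reproduces the published proportions with Wilson CIs", {
  tabs <- cac_example_tables()
  a <- category_accuracy(tabs$ctac_rest_manual_vs_auto)
  expect_equal(a$accuracy, 106 / 128)
  expect_equal(round(100 * a$accuracy, 1), 82.8)
  expect_equal(category_accuracy(tabs$ctac_stress_manual_vs_auto)$accuracy,
               113 / 128)
  expect_equal(round(category_accuracy(tabs$csct_vs_ctac_rest_auto)$accuracy, 2),
               0.71)
  expect_equal(round(category_accuracy(tabs$csct_vs_ctac_stress_auto)$accuracy, 2),
               0.70)
  expect_equal(category_accuracy(diag(7, 4))$accuracy, 1)
  off <- matrix(1, 3, 3) - diag(1, 3)
  expect_equal(category_accuracy(off)$accuracy, 0)
  expect_true(a$accuracy_ci95[1] < a$accuracy &&
                a$accuracy < a$accuracy_ci95[2])
})

test_that("absolute-agreement ICC matches the hand-worked ANOVA example", {
  expect_equal(icc_absolute(cbind(c(1, 3, 5), c(2, 4, 6)))$icc, 8 / 9)
  r <- icc_absolute(cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(r$msr, 8)
  expect_equal(r$msc, 1.5)
  expect_equal(r$mse, 0)
  # identical columns -> perfect agreement
  expect_equal(icc_absolute(cbind(c(2, 9, 4, 7), c(2, 9, 4, 7)))$icc, 1)
  # constant offset: consistency would be 1, absolute agreement is penalized
  x <- c(1, 2, 3, 4, 5)
  r2 <- icc_absolute(cbind(x, x + 100))
  expect_lt(r2$icc, 0.1)
  expect_equal(stats::cor(x, x + 100), 1)
  expect_error(icc_absolute(cbind(c(1, 1, 1), c(1, 1, 1))), "undefined")
  expect_error(icc_absolute(cbind(1:2, 3:4)), "subjects")
})

test_that("signed-rank test matches enumeration and symmetry anchors", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
  r <- wilcoxon_signed_rank(1:6, 1:6 + 1)
  expect_equal(r$p_value, 2 / 64)
  expect_identical(r$method, "exact")
  # antisymmetric differences: statistic at the null centre, p = 1
  r2 <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_equal(r2$statistic, 6 * 7 / 4)
  expect_equal(r2$p_value, 1)
  # agreement with the reference implementation when ties are absent
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
  # large samples switch to the corrected normal approximation
  set.seed(13)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                   exact = FALSE,
                                                   correct = TRUE))$p.value)
})

test_that("z-comparison of agreement estimates behaves like a normal test", {
  tabs <- cac_example_tables()
  k1 <- weighted_kappa(tabs$ctac_rest_manual_vs_auto)
  expect_equal(compare_kappas(k1, k1)$z, 0)
  expect_equal(compare_kappas(k1, k1)$p_value, 1)
  k2 <- weighted_kappa(tabs$csct_vs_ctac_stress_auto)
  cmp <- compare_kappas(k1, k2)
  expect_equal(compare_kappas(k2, k1)$z, -cmp$z)
  # engineered 3-sigma difference -> p ~ 0.0027
  a <- structure(list(kappa = 0.8, kappa_se = 0.03), class = "agreement_result")
  b <- structure(list(kappa = 0.8 - 3 * sqrt(2 * 0.03^2), kappa_se = 0.03),
                 class = "agreement_result")
  expect_equal(compare_kappas(a, b)$p_value, 2 * pnorm(-3))
  # accuracies compare through the same machinery
  acc <- category_accuracy(tabs$ctac_rest_manual_vs_auto)
  expect_equal(compare_agreement(acc, acc)$z, 0)
})

test_that("detection metrics count overlaps per scan", {
  v <- make_volume(c(4, 8, 8), spacing = c(3, 1.35, 1.35))
  v$data[1, 2, 2:3] <- 300
  v$data[3, 6, 5:6] <- 300
  v$data[2, 4, 4:5] <- 300
  ref <- extract_candidates(v)
  expect_length(ref, 3)
  # detections identical to references
  d <- detection_metrics(list(ref), list(ref), list(v))
  expect_equal(d$lesion_sensitivity, 1)
  expect_equal(d$volume_sensitivity, 1)
  expect_equal(d$fp_lesions_per_scan, 0)
  expect_equal(d$fp_volume_per_scan, 0)
  # 2 of 3 found plus one spurious detection
  spur <- make_volume(c(4, 8, 8), spacing = c(3, 1.35, 1.35))
  spur$data[4, 1, 1:2] <- 300
  sp <- extract_candidates(spur)[[1]]
  d2 <- detection_metrics(list(ref), list(c(ref[1:2], list(sp))), list(v))
  expect_equal(d2$lesion_sensitivity, 2 / 3)
  expect_equal(d2$fp_lesions_per_scan, 1)
  expect_equal(d2$fp_volume_per_scan, 2 * prod(v$spacing))
  # no detections at all
  d3 <- detection_metrics(list(ref), list(list()), list(v))
  expect_equal(d3$lesion_sensitivity, 0)
  expect_equal(d3$volume_sensitivity, 0)
  expect_equal(d3$fp_lesions_per_scan, 0)
  # scans without reference lesions only contribute false positives
  d4 <- detection_metrics(list(ref, list()), list(ref, list(sp)),
                          list(v, v))
  expect_equal(d4$lesion_sensitivity, 1)
  expect_equal(d4$fp_lesions_per_scan, 0.5)
  expect_identical(d4$n_scans_with_cac, 1L)
})

test_that("confusion matrices survive the CSV round-trip", {
  m <- cac_example_tables()$csct_vs_ctac_rest_auto
  f <- tempfile(fileext = ".csv")
  write_confusion(m, f)
  expect_identical(unname(read_confusion(f)), unname(m))
  expect_error(check_confusion <- cacscore:::check_confusion(matrix(0, 2, 2)),
               "empty")
})
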