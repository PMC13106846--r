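test_that("Welch t-test matches the closed-form statistic and is symmetric", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  r <- welch_t_test(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(r$t, t_hand, tolerance = 1e-10)
  expect_equal(r$df, df_hand, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  r2 <- welch_t_test(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("AUC: separation, orientation, ties, and sign flip", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("control", "control", "case", "case")), 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c("control", "control", "case", "case")), 0.25)
  expect_equal(roc_auc(rep(1, 6), rep(c("case", "control"), 3)), 0.5)
  expect_error(roc_auc(1:3, rep("case", 3)), "empty")

  set.seed(17)
  for (i in 1:50) {
    sc <- round(rnorm(sample(6:50, 1)), 1)          # rounded: force some ties
    lb <- sample(c("case", "control"), length(sc), replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), auc_naive(sc, lb))
    expect_equal(roc_auc(-sc, lb), 1 - auc_naive(sc, lb))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(29)
  sc <- rnorm(40)
  lb <- sample(c("case", "control"), 40, replace = TRUE, prob = c(0.4, 0.6))
  got <- roc_auc(sc, lb)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = lb, predictor = sc, levels = c("case", "control"),
    direction = "<")))
  expect_equal(got, as.numeric(ref), tolerance = 1e-12)
})

test_that("compare_groups bundles test and AUC; single-subject groups error", {
  sc <- data.frame(subject_id = letters[1:10],
                   label = rep(c("case", "control"), each = 5),
                   score = c(1:5 / 10, 6:10 / 10))
  cmp <- compare_groups(sc, "LZ76", 44, c(60, 100))
  expect_equal(cmp$n_cases, 5)
  expect_equal(cmp$auc, 1.0)
  expect_lt(cmp$p, 0.05)
  expect_error(compare_groups(sc[c(1, 6, 7), ]), ">= 2 subjects")
})

test_that("permuted labels give a calibrated false-positive rate", {
  set.seed(41)
  x <- rnorm(40)
  hits <- 0L
  nperm <- 1000L
  for (i in seq_len(nperm)) {
    lb <- sample(rep(c("case", "control"), each = 20))
    p <- welch_t_test(x[lb == "case"], x[lb == "control"])$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / nperm, 0.03)
  expect_lt(hits / nperm, 0.07)
})

test_that("algorithm ranking: p first, then AUC, then mask code", {
  cmp <- data.frame(estimator = "LZ76", mask = c(3, 1, 2, 9),
                    p = c(0.02, 0.01, 0.02, 0.02),
                    auc = c(0.9, 0.7, 0.9, 0.95))
  rk <- rank_algorithms(cmp)
  expect_equal(rk$mask, c(1, 9, 2, 3))
})

test_that("diagnostic metrics reproduce the printed worked example", {
  m <- diagnostic_metrics(tp = 6, fp = 10, tn = 50, fn = 1)
  expect_equal(round(m$sensitivity, 1), 85.7)
  expect_equal(round(unname(m$sensitivity_ci), 1), c(59.8, 100))
  expect_equal(round(m$specificity, 1), 83.3)
  expect_equal(round(unname(m$specificity_ci), 1), c(73.9, 92.8))
  expect_equal(round(m$ppv, 1), 37.5)
  expect_equal(round(unname(m$ppv_ci), 1), c(13.8, 61.2))
  expect_equal(round(m$npv, 1), 98.0)
  expect_equal(round(unname(m$npv_ci), 1), c(94.2, 100))
  expect_equal(m$cui_positive, (6 / 7) * (6 / 16), tolerance = 1e-12)
})

test_that("diagnostic metrics degenerate cases", {
  m <- diagnostic_metrics(1, 0, 1, 0)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$ppv, 100)
  m2 <- diagnostic_metrics(0, 0, 1, 1)
  expect_false(m2$ppv_defined)
  expect_true(is.na(m2$ppv))
  expect_error(diagnostic_metrics(0, 0, 0, 0), "positive-class")
})

test_that("threshold classification is cases-low oriented", {
  sc <- data.frame(subject_id = letters[1:6],
                   label = c("case", "case", rep("control", 4)),
                   score = c(-0.2, -0.1, 0.1, 0.2, 0.3, 0.4))
  lowest <- classify_threshold(sc, -1)
  expect_equal(lowest$tp + lowest$fp, 0)            # everyone control
  highest <- classify_threshold(sc, 1)
  expect_equal(highest$tn + highest$fn, 0)          # everyone case
  # sweeping Youden's J on this separable set reaches perfect Se and Sp
  best <- NULL
  for (th in sort(unique(sc$score))) {
    cc <- classify_threshold(sc, th)
    j <- cc$tp / (cc$tp + cc$fn) + cc$tn / (cc$tn + cc$fp) - 1
    if (is.null(best) || j > best$j) best <- c(cc, j = j)
  }
  expect_equal(best$j, 1)
})
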