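test_that("Spearman screen flags only strongly positive rank correlations", {
  df <- tibble::tibble(
    up = c(1, 2, 3, 4), lin = c(10, 20, 30, 40), down = c(4, 3, 2, 1))
  sc <- spearman_screen(df)
  row <- function(a, b) sc[sc$feature_a == a & sc$feature_b == b, ]
  expect_equal(row("up", "lin")$rho, 1)
  expect_true(row("up", "lin")$flagged)
  expect_equal(row("up", "down")$rho, -1)
  expect_false(row("up", "down")$flagged) # rule is rho > 0.75, not |rho|
})

test_that("Spearman coefficients match a rank-Pearson oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  sc <- spearman_screen(tibble::tibble(x = x, y = y))
  expect_equal(sc$rho[1], oracle_spearman(x, y))
  expect_equal(sc$rho[1], 0.8)
  expect_true(sc$flagged[1])
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    sc <- spearman_screen(tibble::tibble(a = a, b = b))
    expect_equal(sc$rho[1], oracle_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("constant features are reported as undefined, not dropped", {
  df <- tibble::tibble(x = c(1, 2, 3, 4), k = c(2, 2, 2, 2))
  sc <- spearman_screen(df)
  expect_true(is.na(sc$rho[1]))
  expect_false(sc$flagged[1])
})

test_that("the Welch test reproduces the published group comparison", {
  wt <- welch_test(c(mean = 6.7, sd = 9.3, n = 9),
                   c(mean = -7.1, sd = 4.3, n = 5))
  expect_equal(round(wt$statistic, 2), -3.78)
  expect_equal(round(wt$df, 1), 11.8)
  expect_equal(round(wt$p_adjusted, 3), 0.008)
})

test_that("the Welch test matches stats::t.test on raw samples", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(7, 2); b <- rnorm(5)
    wt <- welch_test(a, b)
    tt <- stats::t.test(b, a)
    expect_equal(unname(wt$statistic), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(unname(wt$df), unname(tt$parameter), tolerance = 1e-10)
    expect_equal(wt$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Welch edge cases behave as declared", {
  expect_equal(welch_test(c(0, 1, 2), c(0, 1, 2))$statistic, 0)
  expect_equal(welch_test(c(0, 1, 2), c(0, 1, 2))$df, 4)
  w1 <- welch_test(c(1, 4, 2, 8), c(3, 3, 1))
  w2 <- welch_test(c(3, 3, 1), c(1, 4, 2, 8))
  expect_equal(w1$statistic, -w2$statistic)
  expect_equal(w1$df, w2$df)
  expect_error(welch_test(c(1), c(1, 2)), class = "dvospt_data_error")
  expect_error(welch_test(c(1, 1), c(2, 2)), class = "dvospt_data_error")
})

test_that("perfectly separated scores give AUC 1 and a cutoff between classes", {
  roc <- roc_analysis(c(2, 3, 4, 0, 1), c(1, 1, 1, 0, 0))
  expect_equal(roc$auc, 1)
  expect_equal(roc$se, 1)
  expect_equal(roc$sp, 1)
  expect_gt(roc$cutoff, 1)
  expect_lt(roc$cutoff, 2)
})

test_that("AUC equals exhaustive pair counting, including ties", {
  scores <- c(1, 3, 4, 0, 2)
  labels <- c(1, 1, 1, 0, 0)
  roc <- roc_analysis(scores, labels)
  expect_equal(roc$auc, oracle_auc(scores, labels))
  expect_equal(roc$auc, 5 / 6)
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 3, by = 0.5), n, replace = TRUE) # forces ties
    roc <- roc_analysis(sc, lab)
    expect_equal(roc$auc, oracle_auc(sc, lab), tolerance = 1e-12)
  }
})

test_that("AUC from trapezoidal integration of the curve matches Mann-Whitney", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- rnorm(n)
    roc <- roc_analysis(sc, lab)
    cur <- roc$curve[order(1 - roc$curve$sp, roc$curve$se), ]
    x <- 1 - cur$sp; y <- cur$se
    trap <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    expect_equal(roc$auc, trap, tolerance = 1e-12)
  }
})

test_that("the Youden cutoff equals an exhaustive threshold search", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(-2, 2, by = 0.25), n, replace = TRUE)
    roc <- roc_analysis(sc, lab)
    best <- oracle_youden(sc, lab)
    expect_equal(roc$cutoff, best$ct)
    expect_equal(roc$j, best$j, tolerance = 1e-12)
  }
})

test_that("the ROC analysis agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:10) {
    lab <- c(1, 0, rbinom(10, 1, 0.5))
    sc <- rnorm(12)
    roc <- roc_analysis(sc, lab)
    ref <- suppressMessages(pROC::roc(lab, sc, direction = "<", quiet = TRUE))
    expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("monotone score transforms preserve AUC and confusion metrics", {
  scores <- c(-1.5, 0.3, 1.2, 2.5, -2.2, -0.4, 0.9)
  labels <- c(1, 1, 1, 1, 0, 0, 0)
  r1 <- roc_analysis(scores, labels)
  r2 <- roc_analysis(scores^3, labels)
  expect_equal(r1$auc, r2$auc)
  p1 <- predict(r1, scores)
  p2 <- predict(r2, scores^3)
  expect_identical(p1, p2)
  cm1 <- confusion_metrics(p1, labels)
  cm2 <- confusion_metrics(p2, labels)
  expect_identical(tidy(cm1), tidy(cm2))
})

test_that("degenerate ROC inputs are rejected", {
  expect_error(roc_analysis(1:5, rep(1, 5)), class = "dvospt_data_error")
  expect_error(roc_analysis(c(NA, NA), c(1, 0)), class = "dvospt_data_error")
})

test_that("confusion metrics and rounded percentages are computed as declared", {
  cm <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(1, 1, 2, 0))
  expect_equal(cm$se, 1)
  expect_equal(cm$sp, 2 / 3)
  expect_equal(cm$sp_pct, 67) # half-up rounding of 66.7

  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect$se_pct, perfect$sp_pct, perfect$ppv_pct, perfect$npv_pct),
               rep(100, 4))

  allpos <- confusion_metrics(rep(1, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(allpos$sp, 0)
  expect_equal(allpos$ppv, 0.3) # prevalence
  expect_true(is.na(allpos$npv))

  expect_error(confusion_metrics(c(1, 2), c(1, 0)), class = "dvospt_data_error")
  expect_error(confusion_metrics(c(1, NA), c(1, 0)), class = "dvospt_data_error")
  expect_error(confusion_metrics(integer(0), integer(0)), class = "dvospt_data_error")
})

test_that("sample size reproduces the closed form and is monotone", {
  expect_equal(sample_size(0.05, 0.04, 1)$n_total, 56)
  expect_equal(sample_size(0.05, 0.5, 1)$n_total, 16) # z_beta = 0
  expect_equal(sample_size(0.05, 0.04, 2)$n_total, 14)
  expect_lte(sample_size(0.05, 0.2, 1)$n_total, sample_size(0.05, 0.1, 1)$n_total)
  expect_lte(sample_size(0.05, 0.04, 1.5)$n_total, sample_size(0.05, 0.04, 1)$n_total)
  expect_gte(sample_size(0.01, 0.04, 1)$n_total, sample_size(0.05, 0.04, 1)$n_total)
  expect_error(sample_size(alpha = 0), class = "dvospt_config_error")
  expect_error(sample_size(beta = 1), class = "dvospt_config_error")
})

test_that("analyze_features ties the statistical layer together", {
  feats <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:8),
    outcome = c(1, 1, 1, 1, 1, 0, 0, 0),
    postpre_gen = c(20, 25, 22, 24, 21, 30, 33, 31),
    fu1pre_gen = c(28, 30, 29, 33, 27, 24, 25, 23),
    fu1post_gen = c(8, 5, 7, 9, 6, -6, -8, -8),
    postpre_loc = c(20, 25, 22, 24, 21, 30, 33, 31),
    fu1pre_loc = c(28, 30, 29, 33, 27, 24, 25, 23),
    fu1post_loc = c(8, 5, 7, 9, 6, -6, -8, -8))
  an <- analyze_features(feats)
  expect_equal(nrow(an$tests), 3)
  expect_equal(an$roc$auc, 1)
  expect_equal(an$confusion$misclassified, 0)
  # identical gen/loc columns must be flagged redundant
  sc <- an$screen
  expect_true(sc$flagged[sc$feature_a == "fu1post_gen" & sc$feature_b == "fu1post_loc"])
  t_row <- an$tests[an$tests$feature == "fu1post_gen", ]
  wt <- welch_test(c(8, 5, 7, 9, 6), c(-6, -8, -8))
  expect_equal(t_row$statistic, wt$statistic)
})
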