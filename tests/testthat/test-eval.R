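test_that("confusion matrices count correctly and conserve totals", {
  expect_equal(unname(confusion_matrix(c(0, 1, 0, 1), c(0, 1, 0, 1))),
               matrix(c(2L, 0L, 0L, 2L), 2))
  expect_equal(unname(confusion_matrix(c(0, 0, 1, 1), c(1, 1, 0, 0))),
               matrix(c(0L, 2L, 2L, 0L), 2))
  set.seed(61)
  yt <- sample(0:3, 1000, TRUE); yp <- sample(0:3, 1000, TRUE)
  expect_equal(sum(confusion_matrix(yt, yp)), 1000)
  expect_error(confusion_matrix(0:3, 0:2), class = "dermtex_shape_error")
})

test_that("binary metrics evaluate the closed-form definitions", {
  # TP=50 FP=10 FN=20 TN=40, positive class = 1 (malignant)
  cm <- matrix(c(40L, 20L, 10L, 50L), 2)
  m <- classification_metrics(cm)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 50 / 70)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 70) / (50 / 60 + 50 / 70))
  expect_equal(m$accuracy, 90 / 120)
})

test_that("metric identities: perfect classifier and harmonic fixed point", {
  cm <- matrix(c(30L, 0L, 0L, 20L), 2)
  m <- classification_metrics(cm)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # precision == recall forces F1 to that common value
  cm2 <- matrix(c(35L, 5L, 5L, 15L), 2)
  m2 <- classification_metrics(cm2)
  expect_equal(m2$precision, m2$recall)
  expect_equal(m2$f1, m2$precision)
})

test_that("multi-class weighted averaging tracks per-class support", {
  cm <- matrix(c(10L, 2L, 0L,
                 1L, 20L, 1L,
                 0L, 3L, 30L), 3, byrow = TRUE)
  pc <- per_class_metrics(cm)
  w <- rowSums(cm) / sum(cm)
  mw <- classification_metrics(cm, averaging = "weighted")
  expect_equal(mw$precision, sum(w * pc$precision))
  expect_equal(mw$f1, sum(w * pc$f1))
  mm <- classification_metrics(cm, averaging = "macro")
  expect_equal(mm$recall, mean(pc$recall))
  expect_equal(mw$accuracy, sum(diag(cm)) / sum(cm))
})

test_that("zero-denominator cells score 0 with a warning instead of crashing", {
  cm <- matrix(c(50L, 0L, 10L, 0L), 2) # nothing predicted positive
  expect_warning(m <- classification_metrics(cm), "zero denominator")
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_error(classification_metrics(matrix(0L, 2, 2)),
               class = "dermtex_input_error")
})

test_that("Welch self-test: any vector against itself gives t = 0, p = 1", {
  set.seed(62)
  for (i in 1:10) {
    x <- sample(0:6, 50, TRUE)
    w <- welch_ttest(x, x)
    expect_equal(w$t, 0)
    expect_equal(w$p_value, 1)
    expect_false(w$significant)
  }
  # both-constant degenerate case, by convention
  wc <- welch_ttest(rep(1, 5), rep(1, 5))
  expect_equal(wc$t, 0); expect_equal(wc$p_value, 1)
})

test_that("Welch statistic is antisymmetric and matches the oracles", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 4, 6, 8, 10)
  w_ab <- welch_ttest(a, b); w_ba <- welch_ttest(b, a)
  expect_equal(w_ab$t, -w_ba$t)
  expect_equal(w_ab$p_value, w_ba$p_value)
  # closed-form statistic and Welch-Satterthwaite df
  expect_equal(w_ab$t, (3 - 6) / sqrt(2.5 / 5 + 10 / 5))
  expect_equal(w_ab$df, 2.5^2 / ((0.5)^2 / 4 + 2^2 / 4))
  # p-value against high-resolution quadrature of the t density
  expect_equal(w_ab$p_value, oracle_t_pvalue(w_ab$t, w_ab$df), tolerance = 1e-10)
  # and against the stock Welch test
  ref <- stats::t.test(a, b)
  expect_equal(w_ab$t, unname(ref$statistic))
  expect_equal(w_ab$df, unname(ref$parameter))
  expect_equal(w_ab$p_value, ref$p.value)
  expect_error(welch_ttest(1, c(1, 2)), class = "dermtex_input_error")
})

test_that("both classifiers separate well-separated Gaussian clouds", {
  set.seed(63)
  tr <- rbind(matrix(rnorm(200, -5), ncol = 2), matrix(rnorm(200, 5), ncol = 2))
  y <- rep(0:1, each = 100)
  te <- rbind(matrix(rnorm(40, -5), ncol = 2), matrix(rnorm(40, 5), ncol = 2))
  yte <- rep(0:1, each = 20)
  for (kind in c("SVM", "XGBOOST")) {
    pred <- fit_predict(kind, tr, y, te, seed = 1)
    expect_equal(mean(pred == yte), 1.0)
    expect_match(attr(pred, "delegate"), tolower(kind))
  }
})

test_that("fit_predict is deterministic and enforces its contracts", {
  set.seed(64)
  tr <- matrix(rnorm(297), ncol = 3); y <- rep(0:2, each = 33)
  te <- matrix(rnorm(30), ncol = 3)
  for (kind in c("SVM", "XGBOOST")) {
    p1 <- fit_predict(kind, tr, y, te, seed = 5)
    p2 <- fit_predict(kind, tr, y, te, seed = 5)
    expect_identical(as.integer(p1), as.integer(p2))
    expect_length(p1, 10)
    expect_true(all(p1 %in% 0:2))
  }
  expect_error(fit_predict("SVM", tr, rep(0L, 99), te, seed = 1),
               class = "dermtex_training_error")
  expect_error(fit_predict("XGBOOST", tr, y, te[, 1:2], seed = 1),
               class = "dermtex_shape_error")
  expect_error(fit_predict("FOREST", tr, y, te, seed = 1),
               class = "dermtex_config_error")
})
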