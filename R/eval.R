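# Classification and evaluation: classifier delegation (SVM via e1071,
# XGBoost via the xgboost package, both at library defaults), confusion
# matrices, accuracy/precision/recall/F1, and Welch's t-test on predicted
# label vectors.

#' Train a classifier and predict test labels
#'
#' Delegates to \pkg{e1071}'s SVM (RBF kernel, library defaults) or to
#' \pkg{xgboost} (library default learner settings, 100 boosting rounds,
#' single thread for determinism). No hyperparameter search is performed.
#'
#' @param kind `"SVM"` or `"XGBOOST"`.
#' @param train_X,train_y Training matrix `N x D` and integer labels
#'   `0..C-1` (at least two classes).
#' @param test_X Test matrix with `D` columns.
#' @param seed Integer seed controlling any training randomness.
#' @return Integer vector of predicted labels, one per test row, with the
#'   delegate package version in attribute `"delegate"`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60, -5), ncol = 2), matrix(rnorm(60, 5), ncol = 2))
#' y <- rep(0:1, each = 30)
#' fit_predict("SVM", X, y, X, seed = 1)
#' @export
fit_predict <- function(kind, train_X, train_y, test_X, seed = 1L) {
  kind <- toupper(kind)
  if (!(kind %in% c("SVM", "XGBOOST"))) {
    stop_dermtex(paste0("unknown classifier: ", kind), "dermtex_config_error")
  }
  if (!is.matrix(train_X)) train_X <- as.matrix(train_X)
  if (!is.matrix(test_X)) test_X <- as.matrix(test_X)
  train_y <- as.integer(train_y)
  classes <- sort(unique(train_y))
  if (length(classes) < 2) {
    stop_dermtex("training set has a single class", "dermtex_training_error")
  }
  if (ncol(train_X) != ncol(test_X)) {
    stop_dermtex(sprintf("feature dimension mismatch: train %d vs test %d",
                         ncol(train_X), ncol(test_X)), "dermtex_shape_error")
  }
  set.seed(mix_seed(seed, if (kind == "SVM") 11L else 13L))
  if (kind == "SVM") {
    # constant columns carry no information and upset e1071's internal scaling
    keep <- apply(train_X, 2, function(c) stats::sd(c) > 0)
    if (!any(keep)) keep[1] <- TRUE
    fit <- e1071::svm(train_X[, keep, drop = FALSE], factor(train_y, levels = classes))
    pred <- predict(fit, test_X[, keep, drop = FALSE])
    out <- as.integer(as.character(pred))
    ver <- as.character(utils::packageVersion("e1071"))
  } else {
    n_class <- length(classes)
    ymap <- match(train_y, classes) - 1L
    params <- if (n_class > 2) {
      list(objective = "multi:softmax", num_class = n_class, nthread = 1)
    } else {
      list(objective = "binary:logistic", nthread = 1)
    }
    fit <- xgboost::xgb.train(params = params,
                              data = xgboost::xgb.DMatrix(train_X, label = ymap),
                              nrounds = 100, verbose = 0)
    raw <- predict(fit, xgboost::xgb.DMatrix(test_X))
    idx <- if (n_class > 2) as.integer(raw) + 1L else as.integer(raw > 0.5) + 1L
    out <- classes[idx]
    ver <- as.character(utils::packageVersion("xgboost"))
  }
  structure(out, delegate = paste0(tolower(kind), " ", ver))
}

#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length integer label vectors.
#' @param n_classes Number of classes `C`; defaults to the largest label + 1.
#' @return `C x C` integer matrix, rows = true class, columns = predicted
#'   class.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop_dermtex("label vectors differ in length", "dermtex_shape_error")
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  C <- n_classes %||% (max(y_true, y_pred) + 1L)
  cm <- matrix(0L, C, C, dimnames = list(true = 0:(C - 1), pred = 0:(C - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total`. For binary tasks (positive class = label 1,
#' the malignant class by convention) precision is `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and F1 their harmonic mean. Multi-class precision,
#' recall and F1 are one-vs-rest per class, combined by weighted (class
#' support; the default) or macro averaging. Cells with a zero denominator
#' (no predicted or no actual positives) are scored 0 with a warning rather
#' than propagating `NaN`.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param averaging `"weighted"` or `"macro"` (multi-class only).
#' @param positive Positive-class label for binary tasks (default `1`).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `averaging`, `n` — all proportions in `[0, 1]`.
#' @export
classification_metrics <- function(cm, averaging = c("weighted", "macro"),
                                   positive = 1L) {
  averaging <- match.arg(averaging)
  total <- sum(cm)
  if (total == 0) stop_dermtex("empty confusion matrix", "dermtex_input_error")
  acc <- sum(diag(cm)) / total
  C <- nrow(cm)
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      rlang::warn(sprintf("zero denominator in %s for class(es) %s; scored 0",
                          what, paste(which(bad) - 1, collapse = ",")))
    }
    ifelse(den == 0, 0, num / den)
  }
  if (C == 2) {
    p <- positive + 1L
    tp <- cm[p, p]
    fp <- sum(cm[, p]) - tp
    fn <- sum(cm[p, ]) - tp
    pr <- safe_div(tp, tp + fp, "precision")
    rc <- safe_div(tp, tp + fn, "recall")
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    avg <- "binary"
  } else {
    tp <- diag(cm)
    pr_c <- safe_div(tp, colSums(cm), "precision")
    rc_c <- safe_div(tp, rowSums(cm), "recall")
    f1_c <- ifelse(pr_c + rc_c == 0, 0, 2 * pr_c * rc_c / (pr_c + rc_c))
    wts <- if (averaging == "weighted") rowSums(cm) / total else rep(1 / C, C)
    pr <- sum(wts * pr_c); rc <- sum(wts * rc_c); f1 <- sum(wts * f1_c)
    avg <- averaging
  }
  tibble::tibble(accuracy = acc, precision = pr, recall = rc, f1 = f1,
                 averaging = avg, n = total)
}

#' Per-class one-vs-rest metrics
#'
#' @inheritParams classification_metrics
#' @return Tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support`.
#' @export
per_class_metrics <- function(cm) {
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  actual_pos <- rowSums(cm)
  pr <- ifelse(pred_pos == 0, 0, tp / pred_pos)
  rc <- ifelse(actual_pos == 0, 0, tp / actual_pos)
  tibble::tibble(
    class = 0:(nrow(cm) - 1L),
    precision = pr, recall = rc,
    f1 = ifelse(pr + rc == 0, 0, 2 * pr * rc / (pr + rc)),
    support = as.integer(actual_pos)
  )
}

#' Welch's two-sample t-test on prediction vectors
#'
#' Unequal-variance t statistic
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch–Satterthwaite degrees of freedom and a two-tailed p-value. The
#' intended inputs are two classifiers' predicted label vectors cast to
#' numerics. Comparing a vector with itself gives `t = 0, p = 1`; if both
#' inputs are constant the statistic is undefined and the same degenerate
#' result `(t = 0, p = 1)` is returned by convention.
#'
#' @param a,b Numeric vectors of length at least 2.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return One-row tibble: `t`, `df`, `p_value`, `significant`.
#' @examples
#' welch_ttest(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' @export
welch_ttest <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop_dermtex("each sample needs at least 2 observations", "dermtex_input_error")
  }
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- 0; df <- NA_real_; p <- 1
  } else {
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble::tibble(t = t, df = df, p_value = p, significant = p < alpha)
}
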