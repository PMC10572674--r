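# Experiment orchestration: images -> color planes -> features (grayscale,
# colored or hybrid) -> optional SMOTE on the training split -> classifier
# -> confusion matrix, metrics and a run report. A process-local feature
# cache keyed by a hash of (data, feature spec) makes grid runs cheap.

the_feature_cache <- new.env(parent = emptyenv())

#' Experiment configuration
#'
#' Declarative description of one classification experiment.
#'
#' @param descriptor Descriptor id (ignored when `hybrid_parts` is given).
#' @param space `"GRAY"` for the classical grayscale pathway or one of
#'   `"LAB"`, `"HSV"`, `"YCBCR"` for colored features.
#' @param classifier `"SVM"` or `"XGBOOST"`.
#' @param hybrid_parts Optional list of `list(descriptor=, space=)` pairs
#'   (at least two) concatenated into a hybrid feature.
#' @param test_fraction Stratified held-out fraction (default 0.2).
#' @param smote Apply SMOTE to the training split after splitting.
#' @param smote_k SMOTE neighbourhood size.
#' @param normalize Per-segment L1 normalisation of histograms.
#' @param seed Top-level seed; split, SMOTE and classifier randomness all
#'   derive from it.
#' @return List of class `dermtex_experiment_config`.
#' @export
experiment_config <- function(descriptor = "LDN", space = "YCBCR",
                              classifier = "XGBOOST", hybrid_parts = NULL,
                              test_fraction = 0.2, smote = FALSE,
                              smote_k = 5L, normalize = TRUE, seed = 42L) {
  if (!is.null(hybrid_parts)) {
    if (length(hybrid_parts) < 2) {
      stop_dermtex("hybrid_parts needs at least two parts", "dermtex_config_error")
    }
    for (p in hybrid_parts) check_descriptor_id(p$descriptor)
  } else {
    check_descriptor_id(descriptor)
  }
  if (!(space %in% color_spaces())) {
    stop_dermtex(paste0("unknown color space: ", space), "dermtex_config_error")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_dermtex("test_fraction must be in (0, 1)", "dermtex_config_error")
  }
  cfg <- list(descriptor = descriptor, space = space,
              classifier = toupper(classifier), hybrid_parts = hybrid_parts,
              test_fraction = test_fraction, smote = isTRUE(smote),
              smote_k = as.integer(smote_k), normalize = isTRUE(normalize),
              seed = as.integer(seed))
  class(cfg) <- "dermtex_experiment_config"
  cfg
}

feature_for_image <- function(img, descriptor, space, dcfg) {
  if (space == "GRAY") gray_feature(img, descriptor, dcfg)
  else colored_feature(img, descriptor, space, dcfg)
}

#' Extract features for every image of a dataset tibble
#'
#' @param dataset Tibble from [make_lesion_dataset()] or [read_manifest()]
#'   (needs an `image` list-column and `class_id`).
#' @param config An [experiment_config()] (its descriptor/space/hybrid and
#'   normalisation fields are used).
#' @param cache Reuse cached features for identical (dataset, feature)
#'   requests within the session.
#' @return Numeric matrix `N x D`, rows in dataset order.
#' @export
extract_features <- function(dataset, config, cache = TRUE) {
  dcfg <- descriptor_config(normalize = config$normalize)
  key <- rlang::hash(list(
    lapply(dataset$image, identity), config$descriptor, config$space,
    config$hybrid_parts, config$normalize
  ))
  if (cache && !is.null(the_feature_cache[[key]])) {
    return(the_feature_cache[[key]])
  }
  feats <- lapply(dataset$image, function(img) {
    if (!is.null(config$hybrid_parts)) {
      hybrid_feature(lapply(config$hybrid_parts, function(p) {
        feature_for_image(img, p$descriptor, p$space %||% config$space, dcfg)
      }))
    } else {
      feature_for_image(img, config$descriptor, config$space, dcfg)
    }
  })
  X <- do.call(rbind, lapply(feats, as.numeric))
  if (cache) the_feature_cache[[key]] <- X
  X
}

#' Clear the in-session feature cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_feature_cache <- function() {
  n <- length(ls(the_feature_cache))
  rm(list = ls(the_feature_cache), envir = the_feature_cache)
  invisible(n)
}

stratified_split <- function(y, test_fraction, seed) {
  set.seed(mix_seed(seed, 7L))
  test_idx <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    if (n_test >= length(idx)) {
      stop_dermtex(sprintf("class %d would have an empty training split", cl),
                   "dermtex_split_error")
    }
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  sort(test_idx)
}

#' Run one classification experiment
#'
#' End-to-end: features are extracted per the config, the data are split
#' stratified by class, SMOTE (optional) balances the training partition
#' only, the classifier is trained and evaluated, and a run report is
#' returned.
#'
#' @param dataset Tibble with `image` list-column and `class_id` labels
#'   (see [make_lesion_dataset()], [read_manifest()]).
#' @param config An [experiment_config()].
#' @param cache Reuse cached features (reports are identical either way).
#' @return Object of class `dermtex_run`: config, feature length, test
#'   indices, true/predicted labels, confusion matrix, metrics tibble,
#'   per-class metrics, delegate version and stage timings. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
run_experiment <- function(dataset, config = experiment_config(), cache = TRUE) {
  if (!all(c("image", "class_id") %in% names(dataset))) {
    stop_dermtex("dataset needs `image` and `class_id` columns", "dermtex_input_error")
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  X <- extract_features(dataset, config, cache = cache)
  y <- as.integer(dataset$class_id)
  timings["features"] <- tic() - t0

  t0 <- tic()
  test_idx <- stratified_split(y, config$test_fraction, config$seed)
  train_X <- X[-test_idx, , drop = FALSE]; train_y <- y[-test_idx]
  test_X <- X[test_idx, , drop = FALSE]; test_y <- y[test_idx]
  if (config$smote) {
    bal <- smote_balance(train_X, train_y, k = config$smote_k,
                         seed = mix_seed(config$seed, 3L))
    train_X <- bal$X; train_y <- bal$y
  }
  timings["split_balance"] <- tic() - t0

  t0 <- tic()
  pred <- fit_predict(config$classifier, train_X, train_y, test_X,
                      seed = config$seed)
  timings["classify"] <- tic() - t0

  cm <- confusion_matrix(test_y, pred, n_classes = length(unique(y)))
  metrics <- classification_metrics(cm)
  structure(list(
    config = config,
    feature_length = ncol(X),
    n_train = length(train_y), n_test = length(test_y),
    test_idx = test_idx,
    y_true = test_y, y_pred = as.integer(pred),
    confusion = cm, metrics = metrics,
    per_class = per_class_metrics(cm),
    delegate = attr(pred, "delegate"),
    timings = timings
  ), class = "dermtex_run")
}

#' @export
print.dermtex_run <- function(x, ...) {
  cfg <- x$config
  feat <- if (!is.null(cfg$hybrid_parts)) {
    paste(vapply(cfg$hybrid_parts, function(p)
      paste0(p$descriptor, "_", p$space %||% cfg$space), ""), collapse = "+")
  } else paste0(cfg$descriptor, "_", cfg$space)
  cat(sprintf("<dermtex_run> %s + %s | features: %d | train/test: %d/%d\n",
              feat, cfg$classifier, x$feature_length, x$n_train, x$n_test))
  m <- x$metrics
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f (%s)\n",
              m$accuracy, m$precision, m$recall, m$f1, m$averaging))
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `dermtex_run`.
#' @param ... Unused.
#' @method tidy dermtex_run
#' @export
tidy.dermtex_run <- function(x, ...) {
  x$per_class
}

#' @rdname run_experiment
#' @method glance dermtex_run
#' @export
glance.dermtex_run <- function(x, ...) {
  cfg <- x$config
  dplyr::bind_cols(
    tibble::tibble(
      descriptor = if (is.null(cfg$hybrid_parts)) cfg$descriptor else "HYBRID",
      space = cfg$space, classifier = cfg$classifier,
      feature_length = x$feature_length,
      n_train = x$n_train, n_test = x$n_test, seed = cfg$seed
    ),
    x$metrics
  )
}

#' @rdname run_experiment
#' @param object A `dermtex_run`.
#' @method autoplot dermtex_run
#' @export
autoplot.dermtex_run <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' Run a grid of experiments
#'
#' One experiment per combination of the supplied descriptors, color spaces
#' and classifiers, on a shared split (same seed).
#'
#' @param dataset Dataset tibble.
#' @param descriptors,spaces,classifiers Character vectors of the grid axes.
#' @param ... Passed to [experiment_config()].
#' @return Tibble with one [glance()] row per combination and a `run`
#'   list-column of the underlying `dermtex_run` objects.
#' @export
run_experiment_grid <- function(dataset, descriptors = descriptor_ids(),
                                spaces = color_spaces(),
                                classifiers = "XGBOOST", ...) {
  grid <- expand.grid(descriptor = descriptors, space = spaces,
                      classifier = classifiers, stringsAsFactors = FALSE)
  runs <- purrr::pmap(grid, function(descriptor, space, classifier) {
    run_experiment(dataset, experiment_config(descriptor = descriptor,
                                              space = space,
                                              classifier = classifier, ...))
  })
  out <- dplyr::bind_rows(lapply(runs, glance))
  out$run <- runs
  out
}

#' Compare two runs with Welch's t-test
#'
#' Applies the two-tailed Welch t-test to the two runs' predicted label
#' vectors (cast to numerics) and tabulates metric deltas. Both runs must
#' have been evaluated on the identical test set.
#'
#' @param run_a,run_b `dermtex_run` objects sharing a test set.
#' @param alpha Significance level (default 0.05).
#' @return List of class `dermtex_comparison`: `welch` (tibble row from
#'   [welch_ttest()]) and `deltas` (metric, value in each run, difference).
#' @export
compare_runs <- function(run_a, run_b, alpha = 0.05) {
  if (!identical(run_a$test_idx, run_b$test_idx) ||
      !identical(run_a$y_true, run_b$y_true)) {
    stop_dermtex("runs were evaluated on different test sets", "dermtex_comparison_error")
  }
  welch <- welch_ttest(run_a$y_pred, run_b$y_pred, alpha = alpha)
  ma <- run_a$metrics; mb <- run_b$metrics
  deltas <- tibble::tibble(
    metric = c("accuracy", "precision", "recall", "f1"),
    run_a = c(ma$accuracy, ma$precision, ma$recall, ma$f1),
    run_b = c(mb$accuracy, mb$precision, mb$recall, mb$f1)
  )
  deltas$delta <- deltas$run_a - deltas$run_b
  structure(list(welch = welch, deltas = deltas), class = "dermtex_comparison")
}

#' @export
print.dermtex_comparison <- function(x, ...) {
  w <- x$welch
  cat(sprintf("Welch t = %.4f, df = %.1f, two-tailed p = %.4f (%s)\n",
              w$t, ifelse(is.na(w$df), NaN, w$df), w$p_value,
              if (w$significant) "significant" else "not significant"))
  print(x$deltas)
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param run A `dermtex_run`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  report <- list(
    config = unclass(run$config),
    feature_length = run$feature_length,
    n_train = run$n_train, n_test = run$n_test,
    metrics = as.list(run$metrics),
    per_class = run$per_class,
    confusion = unname(apply(run$confusion, 1, as.integer, simplify = FALSE)),
    y_true = run$y_true, y_pred = run$y_pred,
    delegate = run$delegate,
    timings = as.list(run$timings)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
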