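#' Classifier configuration
#'
#' Fixes one of the three classifier setups used throughout the evaluation:
#' an MLP with two hidden layers of 64 and 32 units, an RBF-kernel SVM, or
#' kd-tree kNN with five neighbours. Feature standardisation (z-score, fit on
#' the training portion only) is on by default because the band features span
#' orders of magnitude and the RBF-SVM and MLP are scale-sensitive.
#'
#' @param kind `"mlp"`, `"svm"` or `"knn"`.
#' @param standardize Standardise features using training-fold statistics.
#' @param seed Integer seed controlling fold shuffling and MLP initialisation.
#' @param mlp_hidden Hidden layer sizes for the MLP.
#' @param mlp_epochs,mlp_learning_rate,mlp_l2 MLP training regime.
#' @param svm_kernel SVM kernel (radial basis).
#' @param knn_neighbors,knn_algorithm kNN neighbour count and search
#'   structure.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("mlp", "svm", "knn"),
                              standardize = TRUE, seed = 0L,
                              mlp_hidden = c(64L, 32L), mlp_epochs = 300L,
                              mlp_learning_rate = 1e-2, mlp_l2 = 1e-4,
                              svm_kernel = "radial",
                              knn_neighbors = 5L, knn_algorithm = "kd_tree") {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, standardize = isTRUE(standardize), seed = as.integer(seed),
         mlp_hidden = as.integer(mlp_hidden), mlp_epochs = as.integer(mlp_epochs),
         mlp_learning_rate = mlp_learning_rate, mlp_l2 = mlp_l2,
         svm_kernel = svm_kernel, knn_neighbors = as.integer(knn_neighbors),
         knn_algorithm = knn_algorithm),
    class = "classifier_config"
  )
}

train_predict <- function(x_train, y_train, x_test, clf) {
  if (nlevels(droplevels(y_train)) < 2L) {
    abort_validation("a training split contains a single class; cannot fit")
  }
  if (clf$standardize) {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1
    x_train <- sweep(sweep(x_train, 2L, mu), 2L, sdv, `/`)
    x_test <- sweep(sweep(x_test, 2L, mu), 2L, sdv, `/`)
  }
  switch(
    clf$kind,
    mlp = {
      fit <- mlp_fit(x_train, y_train, hidden = clf$mlp_hidden,
                     epochs = clf$mlp_epochs,
                     learning_rate = clf$mlp_learning_rate,
                     l2 = clf$mlp_l2, seed = clf$seed)
      predict(fit, x_test)
    },
    svm = {
      fit <- e1071::svm(x_train, y_train, kernel = clf$svm_kernel,
                        scale = FALSE)
      predict(fit, x_test)
    },
    knn = FNN::knn(x_train, x_test, y_train, k = clf$knn_neighbors,
                   algorithm = clf$knn_algorithm)
  )
}

#' Accuracy and F1 score of a prediction
#'
#' Accuracy is the fraction of correct predictions. For binary labels the F1
#' score is the harmonic mean of precision and recall on the positive (high)
#' class, with F1 = 0 when precision + recall = 0; with three or more classes
#' the macro-averaged F1 is returned.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive Label treated as positive for binary F1; by default any
#'   label starting with `H`/`h` (`HV`, `HA`, `high`).
#' @return Named numeric vector `c(accuracy = , f1 = )`.
#' @export
compute_metrics <- function(y_true, y_pred, positive = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    abort_validation("y_true and y_pred must be equal-length, non-empty")
  }
  acc <- mean(y_true == y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  f1_of <- function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  if (length(classes) <= 2L) {
    if (is.null(positive)) {
      hi <- classes[grepl("^h", classes, ignore.case = TRUE)]
      positive <- if (length(hi) == 1L) hi else classes[length(classes)]
    }
    f1 <- f1_of(positive)
  } else {
    f1 <- mean(vapply(classes, f1_of, numeric(1)))
  }
  c(accuracy = acc, f1 = f1)
}

target_labels <- function(records, target) {
  target <- match.arg(target, c("valence", "arousal"))
  col <- paste0(target, "_label")
  if (!col %in% names(records)) {
    abort_validation(sprintf("records lack a '%s' column", col))
  }
  factor(records[[col]])
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

new_eval_report <- function(target, protocol, results, config) {
  structure(
    list(target = target, protocol = protocol, results = results,
         mean_accuracy = mean(results$accuracy),
         mean_f1 = mean(results$f1), config = config),
    class = "eval_report"
  )
}

#' Stratified k-fold cross-validated classification
#'
#' Splits the feature records into `k` stratified folds (class proportions
#' preserved, shuffling controlled by the classifier seed), fits the
#' configured classifier on each training portion and scores accuracy and F1
#' on the held-out fold. Standardisation statistics are computed on the
#' training folds only. Windows from one trial may land in different folds;
#' use [run_loso()] for the subject-blocked protocol.
#'
#' @param records Feature tibble from [assemble_features()].
#' @param target `"valence"` or `"arousal"`.
#' @param clf A [classifier_config()].
#' @param k Number of folds (default 10).
#' @return An `eval_report` with per-fold accuracy/F1 and their means.
#' @export
run_kfold <- function(records, target = "valence",
                      clf = classifier_config(), k = 10L) {
  y <- target_labels(records, target)
  if (nrow(records) < k) abort_validation("fewer records than folds")
  if (nlevels(droplevels(y)) < 2L) {
    abort_validation("both classes must be present for stratified k-fold")
  }
  x <- as.matrix(records[, feature_cols(records), drop = FALSE])
  fold <- stratified_folds(y, k, clf$seed)
  res <- purrr::map_dfr(seq_len(k), function(f) {
    te <- fold == f
    pred <- train_predict(x[!te, , drop = FALSE], droplevels(y[!te]),
                          x[te, , drop = FALSE], clf)
    m <- compute_metrics(y[te], pred)
    tibble::tibble(unit = sprintf("fold%02d", f), n_test = sum(te),
                   accuracy = m[["accuracy"]], f1 = m[["f1"]])
  })
  new_eval_report(target, "kfold", res, eval_config_snapshot(clf, k = k))
}

#' Leave-one-subject-out cross-validated classification
#'
#' One evaluation unit per subject: the classifier is trained on every other
#' subject's records and tested on all records of the held-out subject. This
#' is the operational test of subject independence — no record of the test
#' subject (and no standardisation statistic derived from it) is seen during
#' training.
#'
#' @inheritParams run_kfold
#' @return An `eval_report` with per-subject accuracy/F1 and their means.
#' @export
run_loso <- function(records, target = "valence", clf = classifier_config()) {
  y <- target_labels(records, target)
  subjects <- unique(records$subject_id)
  if (length(subjects) < 2L) {
    abort_validation("leave-one-subject-out needs at least 2 subjects")
  }
  x <- as.matrix(records[, feature_cols(records), drop = FALSE])
  res <- purrr::map_dfr(subjects, function(s) {
    te <- records$subject_id == s
    y_tr <- droplevels(y[!te])
    if (nlevels(y_tr) < 2L) {
      abort_validation(sprintf(
        "training split excluding subject '%s' contains a single class", s
      ))
    }
    pred <- train_predict(x[!te, , drop = FALSE], y_tr,
                          x[te, , drop = FALSE], clf)
    m <- compute_metrics(y[te], pred)
    tibble::tibble(unit = s, n_test = sum(te),
                   accuracy = m[["accuracy"]], f1 = m[["f1"]])
  })
  new_eval_report(target, "loso", res, eval_config_snapshot(clf))
}

eval_config_snapshot <- function(clf, ...) {
  c(unclass(clf), list(...))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s / %s, %d units: mean accuracy %.3f, mean F1 %.3f (%s)\n",
    x$target, x$protocol, nrow(x$results), x$mean_accuracy, x$mean_f1,
    x$config$kind
  ))
  invisible(x)
}

#' Per-unit results of an evaluation
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per fold or subject: `unit`, `n_test`,
#'   `accuracy`, `f1`.
#' @export
tidy.eval_report <- function(x, ...) x$results

#' One-row summary of an evaluation
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble: target, protocol, classifier, number of units,
#'   mean accuracy and mean F1.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    target = x$target, protocol = x$protocol, classifier = x$config$kind,
    n_units = nrow(x$results),
    mean_accuracy = x$mean_accuracy, mean_f1 = x$mean_f1
  )
}

#' Plot per-unit accuracy of an evaluation
#'
#' Bar chart of per-fold or per-subject accuracy with the mean as a dashed
#' line.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = if (object$protocol == "loso") "held-out subject" else "fold",
      y = "accuracy",
      title = sprintf("%s classification (%s, %s)", object$target,
                      object$protocol, object$config$kind)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
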