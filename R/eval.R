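# Cubic-SVM evaluation under stratified 10-fold cross-validation, and the
# six summary metrics.
#
# The classifier is a third-degree polynomial-kernel SVM, box constraint
# C = 1, one-vs-one multiclass, kernel scale and offset 1 (the inhomogeneous
# cubic kernel (u.v + 1)^3). Inputs are expected already normalized, so the
# wrapper never rescales.

# Run code under a temporary RNG state so seeded internals never disturb the
# caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded stratified fold assignment
#'
#' @param labels Factor of class labels.
#' @param folds Number of folds.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Integer vector of fold ids in `1..folds`, one per observation,
#'   with each class spread as evenly as possible across folds.
#' @export
make_folds <- function(labels, folds = 10L, seed = 1L) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("every class needs >= ", folds, " members for ", folds,
         "-fold stratified CV; offending: ",
         paste(names(counts)[counts < folds], collapse = ", "), call. = FALSE)
  }
  assignment <- integer(length(labels))
  .with_seed(seed, {
    for (cl in levels(labels)) {
      rows <- which(labels == cl)
      assignment[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })
  assignment
}

.fit_cubic_svm <- function(x, y) {
  e1071::svm(x = x, y = y, kernel = "polynomial", degree = 3, gamma = 1,
             coef0 = 1, cost = 1, scale = FALSE)
}

# Pooled misclassification rate of a cubic SVM under precomputed folds.
.cv_error <- function(x, labels, fold_id) {
  wrong <- 0L
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    fit <- .fit_cubic_svm(x[!test, , drop = FALSE], labels[!test])
    pred <- stats::predict(fit, x[test, , drop = FALSE])
    wrong <- wrong + sum(pred != labels[test])
  }
  wrong / length(labels)
}

#' Cross-validated cubic-SVM evaluation
#'
#' Stratified seeded k-fold cross-validation of the cubic SVM; test-fold
#' predictions are pooled into one confusion matrix (rows = true, columns =
#' predicted) from which the six summary metrics are computed.
#'
#' @param x Numeric feature matrix (already normalized / selected).
#' @param labels Class labels, one per row; every class must have at least
#'   `folds` members.
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment (default 1).
#' @return Object of class `ltp_eval_report`: list with `confusion`,
#'   `fold_accuracies` (percent, one per fold), `metrics` (six percentages),
#'   `folds`, `seed`.
#' @export
cross_validate <- function(x, labels, folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  fold_id <- make_folds(labels, folds = folds, seed = seed)
  lev <- levels(labels)
  confusion <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- .fit_cubic_svm(x[!test, , drop = FALSE], labels[!test])
    pred <- stats::predict(fit, x[test, , drop = FALSE])
    confusion <- confusion + unclass(table(labels[test], pred))
    fold_acc[f] <- 100 * mean(pred == labels[test])
  }
  structure(list(confusion = confusion,
                 fold_accuracies = fold_acc,
                 metrics = metrics_from_confusion(confusion),
                 folds = folds, seed = seed),
            class = "ltp_eval_report")
}

#' @export
print.ltp_eval_report <- function(x, ...) {
  cat("Cross-validated cubic-SVM report (", x$folds, "-fold)\n\n", sep = "")
  print(x$confusion)
  cat("\nFold accuracies (%):",
      paste(sprintf("%.2f", x$fold_accuracies), collapse = " "), "\n\n")
  print(round(x$metrics, 2))
  invisible(x)
}

#' Summary metrics of a confusion matrix
#'
#' Computes, as percentages: overall accuracy (trace / total); macro
#' F1-score; average (macro) precision; geometric mean of per-class recalls;
#' sensitivity (macro recall); specificity (macro one-vs-rest specificity).
#' Macro averages are unweighted over classes, appropriate for balanced
#' designs. A class never predicted contributes precision 0 (with a
#' warning), not an error.
#'
#' @param confusion Square nonnegative matrix, rows = true, cols = predicted.
#' @return Named numeric vector: `accuracy`, `f1`, `avg_precision`,
#'   `geometric_mean`, `sensitivity`, `specificity`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  tp <- diag(confusion)
  row_sum <- rowSums(confusion)   # true class sizes
  col_sum <- colSums(confusion)   # predicted class sizes

  if (any(col_sum == 0)) {
    warning("class(es) never predicted: precision counted as 0 for ",
            paste(rownames(confusion)[col_sum == 0], collapse = ", "))
  }
  precision <- ifelse(col_sum > 0, tp / col_sum, 0)
  recall <- ifelse(row_sum > 0, tp / row_sum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tn <- total - row_sum - col_sum + tp
  specificity <- tn / (total - row_sum)

  100 * c(accuracy = sum(tp) / total,
          f1 = mean(f1),
          avg_precision = mean(precision),
          geometric_mean = if (any(recall <= 0)) 0 else exp(mean(log(recall))),
          sensitivity = mean(recall),
          specificity = mean(specificity))
}

#' Accuracy comparison across shallow classifiers
#'
#' Runs decision tree, linear discriminant, naive Bayes, linear / quadratic /
#' cubic SVM, k-nearest-neighbors and bagged trees under identical stratified
#' folds and reports the pooled cross-validated accuracy of each.
#'
#' @param x Numeric feature matrix.
#' @param labels Class labels.
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return data.frame with columns `classifier` and `accuracy` (percent),
#'   one row per classifier.
#' @export
compare_classifiers <- function(x, labels, folds = 10L, seed = 1L) {
  for (pkg in c("rpart", "MASS", "class", "randomForest")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("compare_classifiers needs the ", pkg, " package", call. = FALSE)
    }
  }
  x <- as.matrix(x)
  labels <- factor(labels)
  fold_id <- make_folds(labels, folds = folds, seed = seed)

  svm_runner <- function(kernel, degree = 3) {
    function(xtr, ytr, xte) {
      fit <- e1071::svm(x = xtr, y = ytr, kernel = kernel, degree = degree,
                        gamma = 1, coef0 = 1, cost = 1, scale = FALSE)
      stats::predict(fit, xte)
    }
  }
  runners <- list(
    DT = function(xtr, ytr, xte) {
      df <- data.frame(y = ytr, xtr)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      stats::predict(fit, data.frame(xte), type = "class")
    },
    LD = function(xtr, ytr, xte) {
      keep <- apply(xtr, 2L, function(col) stats::sd(col) > 0)
      fit <- MASS::lda(xtr[, keep, drop = FALSE], grouping = ytr)
      stats::predict(fit, xte[, keep, drop = FALSE])$class
    },
    NB = function(xtr, ytr, xte) {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte)
    },
    LSVM = svm_runner("linear"),
    QSVM = svm_runner("polynomial", degree = 2),
    CSVM = svm_runner("polynomial", degree = 3),
    kNN = function(xtr, ytr, xte) class::knn(xtr, xte, ytr, k = 1),
    BT = function(xtr, ytr, xte) {
      fit <- .with_seed(seed, randomForest::randomForest(
        xtr, ytr, ntree = 100, mtry = ncol(xtr)))
      stats::predict(fit, xte)
    }
  )

  acc <- vapply(runners, function(run) {
    correct <- 0L
    for (f in seq_len(folds)) {
      test <- fold_id == f
      pred <- run(x[!test, , drop = FALSE], labels[!test],
                  x[test, , drop = FALSE])
      correct <- correct + sum(pred == labels[test])
    }
    100 * correct / length(labels)
  }, numeric(1))

  data.frame(classifier = names(runners), accuracy = unname(acc))
}
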