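# Three-stage hybrid feature selection: threshold pruning of constant
# features, positive-ReliefF pruning, then an iterative NCA subset search
# scored by the cross-validated loss of the cubic SVM.
#
# All stage outputs are recorded in a selection trace whose index sets are
# nested (final subset within ReliefF survivors within threshold survivors)
# and always refer to columns of the ORIGINAL matrix.

#' Column-wise min-max normalization
#'
#' Maps every column to `[0, 1]` via `(x - min) / (max - min)`. A constant
#' column becomes all zeros (the 0/0 guard), which is exactly what the
#' threshold stage then removes.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with columns in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2L, min)
  rng <- apply(x, 2L, max) - mins
  out <- sweep(x, 2L, mins, "-")
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out
}

#' Threshold-based feature pruning
#'
#' Keeps column j iff its column sum exceeds `beta`. On a min-max normalized
#' matrix with the default `beta = 0` this removes exactly the constant
#' (all-zero) columns and nothing else.
#'
#' @param x Min-max normalized numeric matrix.
#' @param beta Threshold on column sums (default 0).
#' @return List with `x` (pruned matrix) and `indices` (kept columns).
#' @export
threshold_select <- function(x, beta = 0) {
  x <- as.matrix(x)
  keep <- which(colSums(x) > beta)
  if (length(keep) == 0L) {
    stop("threshold selection removed every feature (all columns constant?)",
         call. = FALSE)
  }
  list(x = x[, keep, drop = FALSE], indices = keep)
}

#' Keep strictly positive-weight features
#'
#' @param x Numeric matrix.
#' @param weights One weight per column (e.g. from [relieff_weights()]).
#' @return List with `x` (kept columns) and `indices`.
#' @export
positive_select <- function(x, weights) {
  x <- as.matrix(x)
  stopifnot(length(weights) == ncol(x))
  keep <- which(weights > 0)
  if (length(keep) == 0L) {
    stop("no feature has a strictly positive weight", call. = FALSE)
  }
  list(x = x[, keep, drop = FALSE], indices = keep)
}

# Symmetric factor Z (n x r) of a PSD Gram matrix G = Z Z', dropping
# numerically null eigendirections.
.gram_factor <- function(gram) {
  e <- eigen(gram, symmetric = TRUE)
  tol <- max(e$values, 0) * length(e$values) * .Machine$double.eps
  keep <- e$values > tol
  if (!any(keep)) return(matrix(0, nrow(gram), 1L))
  e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = sum(keep))
}

#' Iterative NCA subset search
#'
#' Computes NCA feature weights once, ranks features by descending weight
#' (stable ties), and for each candidate size k in `[kmin, kmax]` evaluates
#' the top-k subset's misclassification rate with the loss classifier — the
#' cubic SVM under seeded stratified `folds`-fold cross-validation, the same
#' folds reused for every k. Each candidate is trained on an n-column Gram
#' factor of the subset (an exact reformulation for kernel machines, see
#' the implementation note in the source), so the sweep's cost does not grow
#' with k. Returns the loss curve and the minimum-loss subset; equal losses
#' break toward the smallest k.
#'
#' @param x Numeric matrix (normalized, pruned upstream).
#' @param labels Class labels.
#' @param kmin,kmax Candidate subset-size bounds (defaults 100 and 1000).
#'   With fewer than `kmin` columns available both bounds are clamped to the
#'   column count (with a message) unless `clamp = FALSE`.
#' @param folds CV folds for the loss classifier (default 10).
#' @param seed Fold-assignment seed.
#' @param clamp Allow clamping the bounds to the available feature count.
#' @return List: `order` (ranking of columns by weight), `nca_weights`,
#'   `loss_curve` (one loss per candidate k), `candidate_k`, `chosen_k`,
#'   `indices` (columns of `x` in the chosen subset).
#' @export
inca_select <- function(x, labels, kmin = 100L, kmax = 1000L, folds = 10L,
                        seed = 1L, clamp = TRUE) {
  x <- as.matrix(x)
  labels <- factor(labels)
  p <- ncol(x)
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  stopifnot(kmin >= 1L, kmax >= kmin)
  if (p < kmin) {
    if (!clamp) {
      stop("only ", p, " features available but kmin = ", kmin, call. = FALSE)
    }
    message("clamping INCA bounds to the ", p, " available features")
    kmin <- kmax <- p
  }
  kmax <- min(kmax, p)
  kmin <- min(kmin, kmax)

  w <- nca_weights(x, labels)
  ord <- order(w, decreasing = TRUE)  # stable: ties keep column order
  fold_id <- make_folds(labels, folds = folds, seed = seed)

  # The polynomial kernel sees the data only through the Gram matrix, so
  # training on any factor Z with Z Z' = G_k is the same machine as training
  # on the top-k features. Growing G_k one rank-1 update per candidate k and
  # refactoring (n x n eigendecomposition) keeps the cost of each of the 901
  # candidate evaluations independent of k.
  xs <- x[, ord, drop = FALSE]
  gram <- tcrossprod(xs[, seq_len(kmin), drop = FALSE])
  ks <- kmin:kmax
  loss <- vapply(ks, function(k) {
    if (k > kmin) gram <<- gram + tcrossprod(xs[, k])
    .cv_error(.gram_factor(gram), labels, fold_id)
  }, numeric(1))

  best <- which.min(loss)  # first minimum = smallest k on ties
  chosen_k <- ks[best]
  list(order = ord, nca_weights = w, loss_curve = loss, candidate_k = ks,
       chosen_k = chosen_k, indices = sort(ord[seq_len(chosen_k)]))
}

#' Three-stage hybrid feature selection
#'
#' Chains min-max normalization, threshold pruning, positive-ReliefF pruning
#' and the iterative NCA search, recording every stage in a selection trace.
#' All index sets refer to columns of the input matrix and are nested:
#' `final_indices` within `kept_after_relieff` within `kept_after_threshold`.
#'
#' @param x Numeric feature matrix, observations x features.
#' @param labels Class labels (>= 2 classes, >= `folds` rows per class).
#' @param beta Threshold for the first stage (default 0).
#' @param kmin,kmax INCA subset-size bounds (defaults 100, 1000).
#' @param folds,seed Loss-classifier CV configuration.
#' @param relieff_k Neighbors for ReliefF (default 10).
#' @return Object of class `ltp_selection_trace`: list with
#'   `kept_after_threshold`, `relieff_weights`, `kept_after_relieff`,
#'   `nca_weights`, `loss_curve`, `candidate_k`, `chosen_k`,
#'   `final_indices`, `x_selected` (normalized matrix restricted to the
#'   final subset), and the configuration used.
#' @export
tsrfinca <- function(x, labels, beta = 0, kmin = 100L, kmax = 1000L,
                     folds = 10L, seed = 1L, relieff_k = 10L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes", call. = FALSE)

  xn <- minmax_normalize(x)
  s1 <- threshold_select(xn, beta = beta)
  wrf <- relieff_weights(s1$x, labels, k = relieff_k)
  s2 <- positive_select(s1$x, wrf)
  kept2 <- s1$indices[s2$indices]
  s3 <- inca_select(s2$x, labels, kmin = kmin, kmax = kmax, folds = folds,
                    seed = seed)
  final <- sort(kept2[s3$indices])

  structure(list(
    kept_after_threshold = s1$indices,
    relieff_weights = wrf,
    kept_after_relieff = kept2,
    nca_weights = s3$nca_weights,
    loss_curve = s3$loss_curve,
    candidate_k = s3$candidate_k,
    chosen_k = s3$chosen_k,
    final_indices = final,
    x_selected = xn[, final, drop = FALSE],
    config = list(beta = beta, kmin = kmin, kmax = kmax, folds = folds,
                  seed = seed, relieff_k = relieff_k)
  ), class = "ltp_selection_trace")
}

#' @export
print.ltp_selection_trace <- function(x, ...) {
  cat("TSRFINCA selection trace\n")
  cat("  after threshold :", length(x$kept_after_threshold), "features\n")
  cat("  after ReliefF   :", length(x$kept_after_relieff), "features\n")
  cat("  INCA candidates :", length(x$loss_curve), "subset sizes\n")
  cat("  chosen subset   :", x$chosen_k, "features (loss",
      sprintf("%.4f", min(x$loss_curve)), ")\n")
  invisible(x)
}

#' Persist a selection trace as JSON (plus the loss curve as CSV)
#'
#' @param trace `ltp_selection_trace` object.
#' @param json_path Output JSON path.
#' @param loss_csv Optional CSV path for the (k, loss) curve.
#' @return Invisibly, `json_path`.
#' @export
write_selection_trace <- function(trace, json_path, loss_csv = NULL) {
  out <- trace[c("kept_after_threshold", "relieff_weights",
                 "kept_after_relieff", "nca_weights", "loss_curve",
                 "candidate_k", "chosen_k", "final_indices", "config")]
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(loss_csv)) {
    utils::write.csv(data.frame(k = trace$candidate_k, loss = trace$loss_curve),
                     loss_csv, row.names = FALSE)
  }
  invisible(json_path)
}
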