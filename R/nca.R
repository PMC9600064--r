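# R wrapper around the C++ NCA objective.

# Mean pairwise absolute difference of a vector, O(n log n) via the sorted
# identity: sum_{i<j} |x_i - x_j| = sum_i (2i - n - 1) x_(i).
.mean_pairwise_absdiff <- function(x) {
  n <- length(x)
  s <- sort(x)
  sum((2 * seq_len(n) - n - 1) * s) / (n * (n - 1) / 2)
}

#' Neighborhood component analysis feature weights
#'
#' Learns one nonnegative weight per feature by maximizing the expected
#' leave-one-out soft-neighbor classification accuracy under the weighted
#' Manhattan metric `d_w(i,j) = sum_r w_r^2 |x_ir - x_jr|`, with an L2
#' penalty `lambda * sum(w^2)` that drives uninformative features toward
#' zero. Optimization is deterministic: all weights start at the common
#' value that makes the mean pairwise weighted distance equal 1 (so the
#' soft-neighbor assignments start well away from their saturated regime
#' even with thousands of features), and L-BFGS-B (bounded below by 0) runs
#' to a fixed projected-gradient tolerance; identical inputs always give
#' identical weights. The weights are used for ranking in the iterative
#' subset search.
#'
#' @param x Numeric matrix, observations x features (normalized upstream).
#' @param labels Class labels, one per row.
#' @param lambda Regularization strength; default `1 / nrow(x)`.
#' @param pgtol Projected-gradient convergence tolerance (default 1e-6).
#' @param maxit Maximum L-BFGS-B iterations (default 60).
#' @return Numeric vector of nonnegative feature weights.
#' @export
nca_weights <- function(x, labels, lambda = 1 / nrow(x), pgtol = 1e-6,
                        maxit = 60L) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  if (length(y) != nrow(x)) stop("labels must match rows of x", call. = FALSE)
  k <- ncol(x)
  # L-BFGS-B requests fn and gr at the same point; cache one evaluation
  cache <- new.env(parent = emptyenv())
  eval_at <- function(w) {
    if (is.null(cache$w) || !identical(w, cache$w)) {
      cache$res <- nca_objective(x, y, w, lambda)
      cache$w <- w
    }
    cache$res
  }
  fn <- function(w) -eval_at(w)$value
  gr <- function(w) -eval_at(w)$gradient
  mean_dist <- sum(apply(x, 2L, .mean_pairwise_absdiff))
  w0 <- rep(if (mean_dist > 0) 1 / sqrt(mean_dist) else 1, k)
  fit <- stats::optim(w0, fn = fn, gr = gr, method = "L-BFGS-B",
                      lower = rep(0, k),
                      control = list(maxit = maxit, pgtol = pgtol))
  fit$par
}
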