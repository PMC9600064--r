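# Multiclass ReliefF feature weighting.
#
# Exhaustive variant: every observation serves as a reference instance, so
# the weights are deterministic with no sampling seed. Neighbors are found
# with Manhattan distance on range-scaled features; per-feature differences
# use the same range scaling, so weights lie in [-1, 1]. Miss contributions
# from each foreign class are weighted by P(class) / (1 - P(reference
# class)), the standard prior correction.

#' ReliefF feature weights
#'
#' Scores each feature by how well it separates nearest same-class (hit)
#' from nearest different-class (miss) observations: weights increase with
#' the mean feature difference to the nearest misses and decrease with the
#' mean difference to the nearest hits. A feature constant across all rows
#' gets weight 0; duplicated columns get identical weights.
#'
#' @param x Numeric matrix, observations x features.
#' @param labels Class labels, one per row (coerced to factor); every class
#'   must have at least 2 members.
#' @param k Number of nearest hits/misses per reference instance (default
#'   10, clamped per class when fewer are available).
#' @return Numeric vector of one weight per feature.
#' @export
relieff_weights <- function(x, labels, k = 10L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x)
  if (length(labels) != n) stop("labels must match rows of x", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every class needs >= 2 members for ReliefF; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  rng <- apply(x, 2L, function(col) diff(range(col)))
  scl <- ifelse(rng > 0, rng, 1)
  xs <- sweep(x, 2L, scl, "/")  # range-scaled; constant cols contribute 0

  d <- as.matrix(stats::dist(xs, method = "manhattan"))
  priors <- as.numeric(counts) / n
  names(priors) <- names(counts)
  classes <- levels(labels)
  class_rows <- split(seq_len(n), labels)

  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    yi <- as.character(labels[i])
    for (cl in classes) {
      rows <- setdiff(class_rows[[cl]], i)
      kk <- min(k, length(rows))
      if (kk == 0L) next
      nb <- rows[order(d[i, rows])][seq_len(kk)]
      mean_diff <- colMeans(abs(xs[nb, , drop = FALSE] -
                                  rep(xs[i, ], each = kk)))
      if (cl == yi) {
        w <- w - mean_diff
      } else {
        w <- w + (priors[[cl]] / (1 - priors[[yi]])) * mean_diff
      }
    }
  }
  w / n
}
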