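# The L-tetrolet textural operator.
#
# A 16-sample sliding window is arranged row-major into a 4x4 matrix
# (V1..V4 = row 1, ..., V13..V16 = row 4). Two L-tetromino templates, P1 and
# P2, each partition the 16 cells into four roles a, b, c, d of four cells.
# Eight sign comparisons per template (a vs c, then b vs d) give an 8-bit
# code, bit k carrying weight 2^(k-1); the two code streams over all windows
# are histogrammed into 2 x 256 = 512 raw-count features.

#' Cell-index table of the two L-tetrolet patterns
#'
#' Returns, for each pattern (`p1`, `p2`) and role (`a`, `b`, `c`, `d`), the
#' four cell indices (1..16, row-major in the 4x4 window matrix) that the
#' role occupies. Within each pattern the sixteen role cells cover every cell
#' exactly once.
#'
#' @return Nested list: `tetrolet_pattern_table()$p1$a` is an integer vector
#'   of four cell indices, and likewise for the other roles and `p2`.
#' @export
tetrolet_pattern_table <- function() {
  list(
    p1 = list(a = c(1L, 5L, 9L, 10L),
              b = c(4L, 3L, 2L, 6L),
              c = c(16L, 12L, 8L, 7L),
              d = c(13L, 14L, 15L, 11L)),
    p2 = list(a = c(1L, 5L, 6L, 7L),
              b = c(8L, 4L, 3L, 2L),
              c = c(9L, 13L, 14L, 15L),
              d = c(16L, 12L, 11L, 10L))
  )
}

#' Binary comparison (signum) bit
#'
#' Returns 1 if `p1 - p2 >= 0`, else 0. Ties produce 1, which is what makes
#' a constant window emit code 255 on both patterns.
#'
#' @param p1,p2 Finite numeric scalars (or equal-length vectors, compared
#'   elementwise).
#' @return Integer 0/1 (vectorised).
#' @export
signum_bit <- function(p1, p2) {
  as.integer(p1 - p2 >= 0)
}

#' Arrange a 16-sample block as a 4x4 window matrix
#'
#' Row-major fill: cell `V_t` equals `block[t]`, so `V1..V4` form the first
#' row. Cell index t of the pattern table addresses `block[t]` directly.
#'
#' @param block Numeric vector of exactly 16 samples.
#' @return 4x4 numeric matrix.
#' @export
window_to_matrix <- function(block) {
  if (length(block) != 16L) {
    stop("block must contain exactly 16 samples, got ", length(block),
         call. = FALSE)
  }
  matrix(block, nrow = 4L, ncol = 4L, byrow = TRUE)
}

#' Compute the two 8-bit pattern codes of one window
#'
#' For each pattern, bits 1..4 compare role `a` against role `c` cellwise and
#' bits 5..8 compare role `b` against role `d`; bit k has weight `2^(k-1)`.
#'
#' @param mat 4x4 numeric window matrix (see [window_to_matrix()]).
#' @param table Pattern index table, by default [tetrolet_pattern_table()].
#' @return Integer vector `c(code1, code2)`, each in 0..255.
#' @examples
#' pattern_codes(window_to_matrix(1:16))   # c(12, 0)
#' pattern_codes(window_to_matrix(rep(7, 16)))  # c(255, 255)
#' @export
pattern_codes <- function(mat, table = tetrolet_pattern_table()) {
  v <- as.vector(t(mat))  # back to block order: v[t] = V_t
  w <- 2L^(0:7)
  vapply(table, function(p) {
    bits <- c(signum_bit(v[p$a], v[p$c]), signum_bit(v[p$b], v[p$d]))
    sum(bits * w)
  }, numeric(1), USE.NAMES = FALSE)
}

# Vectorised code streams for all sliding windows of a signal.
# Returns a list(map1, map2) of integer code sequences of length L - 15.
.tetrolet_maps <- function(x, table = tetrolet_pattern_table()) {
  n <- length(x) - 15L
  # blocks[i, t] = x[i + t - 1]: row i is the i-th window
  blocks <- matrix(0, nrow = n, ncol = 16L)
  for (t in 1:16) blocks[, t] <- x[t:(t + n - 1L)]
  w <- 2^(0:7)
  lapply(table, function(p) {
    left <- blocks[, c(p$a, p$b), drop = FALSE]
    right <- blocks[, c(p$c, p$d), drop = FALSE]
    bits <- (left - right) >= 0
    as.integer(bits %*% w)
  })
}

#' L-tetrolet textural features of a 1-D signal
#'
#' Slides a 16-sample window with stride 1 over the signal (windows
#' `i = 1 .. L-15`), computes the two pattern codes of each window, and
#' returns the concatenated 256-bin histograms of the two code streams:
#' features 1..256 are the counts of codes 0..255 under pattern P1, features
#' 257..512 under P2. Histograms are raw counts, so each half sums to
#' `L - 15`. The features depend only on pairwise sample orderings, hence are
#' invariant under any strictly increasing affine rescaling of the signal.
#'
#' @param x Numeric vector of length >= 16 with finite values.
#' @return Numeric vector of 512 nonnegative counts.
#' @examples
#' f <- tetrolet_features(sin(1:100))
#' sum(f[1:256])    # 85 windows
#' @export
tetrolet_features <- function(x) {
  .check_signal(x, min_len = 16L)
  maps <- .tetrolet_maps(x)
  c(tabulate(maps[[1]] + 1L, nbins = 256L),
    tabulate(maps[[2]] + 1L, nbins = 256L))
}
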