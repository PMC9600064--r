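# Pairwise pooling decomposers.
#
# All four operators act on non-overlapping blocks of two samples; a trailing
# unpaired sample is discarded (no padding, so histograms downstream never see
# artificial amplitudes). Output length is always floor(L/2).

.check_signal <- function(x, min_len = 2L, what = "signal") {
  if (!is.numeric(x)) {
    stop(sprintf("%s must be numeric", what), call. = FALSE)
  }
  if (length(x) < min_len) {
    stop(sprintf("%s must have at least %d samples, got %d",
                 what, min_len, length(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  invisible(x)
}

# Split x into its non-overlapping pairs: a 2 x floor(L/2) matrix.
.pairs <- function(x) {
  n <- length(x) %/% 2L
  matrix(x[seq_len(2L * n)], nrow = 2L)
}

#' Maximum pooling of a 1-D signal
#'
#' Halves a signal by taking the maximum of each non-overlapping pair of
#' samples. This is the level-update decomposer of the multilevel feature
#' extractor: applying it repeatedly produces the coarser signals on which
#' deeper-level features are computed.
#'
#' @param x Numeric vector of length >= 2 with finite values.
#' @return Numeric vector of length `floor(length(x) / 2)`. A trailing
#'   unpaired sample is discarded.
#' @examples
#' max_pool(c(1, 4, 2, 3))  # c(4, 3)
#' max_pool(c(1, 2, 3))     # c(2): trailing sample dropped
#' @seealso [decompose_triple()] for the three companion pooling operators.
#' @export
max_pool <- function(x) {
  .check_signal(x)
  p <- .pairs(x)
  pmax(p[1L, ], p[2L, ])
}

#' Pooling decomposition into average, absolute-average and absolute-maximum
#' signals
#'
#' Decomposes a signal into the three half-length companion signals used at
#' each level of the multilevel extractor:
#' \describe{
#'   \item{m1}{average pooling, the mean of each pair;}
#'   \item{m2}{absolute average pooling, `|mean|` of each pair;}
#'   \item{m3}{absolute maximum pooling, `max(|x_i|, |x_{i+1}|)`.}
#' }
#' `m2` and `m3` are nonnegative by construction and `m2 <= m3` elementwise
#' (the magnitude of a mean never exceeds the larger magnitude).
#'
#' @param x Numeric vector of length >= 2 with finite values.
#' @return A list with numeric components `m1`, `m2`, `m3`, each of length
#'   `floor(length(x) / 2)`.
#' @examples
#' decompose_triple(c(1, 3, -2, 4))$m1  # c(2, 1)
#' decompose_triple(c(-3, 1))           # m2 = 1, m3 = 3
#' @export
decompose_triple <- function(x) {
  .check_signal(x)
  p <- .pairs(x)
  m1 <- (p[1L, ] + p[2L, ]) / 2
  list(m1 = m1, m2 = abs(m1), m3 = pmax(abs(p[1L, ]), abs(p[2L, ])))
}
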