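# Independent brute-force oracles used to cross-check the vectorised
# implementations. They walk the definitions literally, one element at a
# time, and share no code with the package internals.

# Literal pattern-code walker: index table written out digit by digit,
# scalar loops only.
oracle_pattern_codes <- function(block16) {
  stopifnot(length(block16) == 16)
  roles <- list(
    list(a = c(1, 5, 9, 10), b = c(4, 3, 2, 6),
         c = c(16, 12, 8, 7), d = c(13, 14, 15, 11)),
    list(a = c(1, 5, 6, 7), b = c(8, 4, 3, 2),
         c = c(9, 13, 14, 15), d = c(16, 12, 11, 10)))
  out <- numeric(2)
  for (t in 1:2) {
    bits <- integer(8)
    for (k in 1:4) {
      bits[k] <- if (block16[roles[[t]]$a[k]] - block16[roles[[t]]$c[k]] >= 0) 1 else 0
      bits[k + 4] <- if (block16[roles[[t]]$b[k]] - block16[roles[[t]]$d[k]] >= 0) 1 else 0
    }
    code <- 0
    for (k in 1:8) code <- code + bits[k] * 2^(k - 1)
    out[t] <- code
  }
  out
}

# Scalar-loop histogram feature oracle.
oracle_tetrolet_features <- function(x) {
  h1 <- integer(256); h2 <- integer(256)
  for (i in seq_len(length(x) - 15)) {
    codes <- oracle_pattern_codes(x[i:(i + 15)])
    h1[codes[1] + 1] <- h1[codes[1] + 1] + 1
    h2[codes[2] + 1] <- h2[codes[2] + 1] + 1
  }
  c(h1, h2)
}

# Tiny balanced toy matrix for selector tests: each planted informative
# column gets its own class-mean pattern (so they are not redundant copies),
# the rest are pure noise.
make_planted_matrix <- function(n_per_class = 12, n_classes = 3,
                                n_informative = 5, n_noise = 20,
                                shift = 2, seed = 11) {
  n <- n_per_class * n_classes
  y <- gl(n_classes, n_per_class, labels = paste0("c", seq_len(n_classes)))
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (n_informative + n_noise)), nrow = n)
    for (j in seq_len(n_informative)) {
      x[, j] <- x[, j] + shift * sample(n_classes)[as.integer(y)]
    }
    list(x = x, labels = y, informative = seq_len(n_informative))
  })
}
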