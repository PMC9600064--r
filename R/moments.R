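# The 18 statistical moments applied to signals and to textural feature
# vectors. Entries 13-15 repeat earlier entries; the list is kept at length
# 18 so the per-signal feature block is always 512 + 18 + 18 = 548 long.
#
# The entropy entries (12, 16, 18) use the normalized-energy distribution
# p_j = x_j^2 / sum(x^2), natural logarithm, with zero-probability terms
# contributing 0 and an all-zero signal giving 0 for all three.

#' The 18 statistical moments of a numeric vector
#'
#' Computes, in fixed order: (1) mean; (2) sum of absolute deviations from
#' the mean divided by n-1; (3) max; (4) min; (5) median; (6) population
#' variance; (7) mean of squares; (8) mean absolute deviation; (9) range
#' (max - min); (10) max - median; (11) mean absolute value; (12) log-energy
#' entropy `-sum(log(p_j^2))` over nonzero terms; (13) range again; (14) min
#' again; (15) entry 2 again; (16) Shannon entropy `-sum(p_j log p_j)`;
#' (17) energy `sum(x^2)`; (18) `-sum(p_j^2 log p_j^2)`; with
#' `p_j = x_j^2 / sum(x^2)`.
#'
#' Entries 13-15 duplicate earlier entries; the fixed length of 18 is part of
#' the feature-layout contract (each signal contributes 18 moments of itself
#' plus 18 moments of its 512 textural features).
#'
#' @param x Numeric vector of length >= 2 with finite values.
#' @return Numeric vector of length 18.
#' @examples
#' m <- compute_moments(c(1, 2, 3, 4))
#' m[c(1, 3, 4, 6, 17)]  # mean 2.5, max 4, min 1, variance 1.25, energy 30
#' @export
compute_moments <- function(x) {
  .check_signal(x, min_len = 2L, what = "moment input")
  n <- length(x)
  mu <- mean(x)
  mx <- max(x)
  mn <- min(x)
  md <- stats::median(x)
  absdev <- abs(x - mu)
  energy <- sum(x^2)

  if (energy > 0) {
    p <- x^2 / energy
    pp <- p[p > 0]
    log_energy_ent <- -sum(log(pp^2))
    shannon_ent <- -sum(pp * log(pp))
    sq_ent <- -sum(pp^2 * log(pp^2))
  } else {
    log_energy_ent <- shannon_ent <- sq_ent <- 0
  }

  c(mu,
    sum(absdev) / (n - 1),
    mx,
    mn,
    md,
    sum((x - mu)^2) / n,
    mean(x^2),
    mean(absdev),
    mx - mn,
    mx - md,
    mean(abs(x)),
    log_energy_ent,
    mx - mn,
    mn,
    sum(absdev) / (n - 1),
    shannon_ent,
    energy,
    sq_ent)
}
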