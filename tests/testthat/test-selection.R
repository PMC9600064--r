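test_that("min-max normalization maps columns to [0,1] with constant guard", {
  expect_equal(minmax_normalize(cbind(c(2, 4, 6))), cbind(c(0, 0.5, 1)))
  expect_equal(minmax_normalize(cbind(c(5, 5, 5))), cbind(c(0, 0, 0)))
  expect_equal(minmax_normalize(cbind(c(0, 1))), cbind(c(0, 1)))
  withr::with_seed(2, {
    x <- matrix(rnorm(200), 10)
    xn <- minmax_normalize(x)
    expect_true(all(xn >= 0 & xn <= 1))
    expect_equal(apply(xn, 2, min), rep(0, 20))
    expect_equal(apply(xn, 2, max), rep(1, 20))
  })
})

test_that("threshold pruning removes exactly the constant columns", {
  x <- cbind(c(5, 5, 5), c(1, 2, 3), c(0, 1, 4))
  sel <- threshold_select(minmax_normalize(x))
  expect_equal(sel$indices, c(2L, 3L))
  expect_error(threshold_select(minmax_normalize(cbind(c(1, 1), c(2, 2)))),
               "every feature")
  withr::with_seed(14, {
    x <- minmax_normalize(matrix(rnorm(500), 10))
    expect_equal(threshold_select(x)$indices, 1:50)
  })
})

test_that("ReliefF ranks a separating feature above noise, zeros constants", {
  # fixed 8-row toy: feature 1 separates the classes perfectly,
  # feature 2 is noise, feature 3 constant, feature 4 duplicates 2
  x <- cbind(c(0, 0, 0, 0, 1, 1, 1, 1),
             c(0.1, 0.9, 0.4, 0.6, 0.2, 0.8, 0.3, 0.7),
             rep(0.5, 8))
  x <- cbind(x, x[, 2])
  y <- gl(2, 4)
  w <- relieff_weights(x, y, k = 3)
  expect_gt(w[1], w[2])
  expect_gt(w[1], 0)
  expect_equal(w[3], 0)
  expect_equal(w[2], w[4])
  expect_error(relieff_weights(x[1:5, ], y[1:5]), ">= 2 members")
})

test_that("positive selection keeps strictly positive weights only", {
  x <- matrix(1:12, 4)
  sel <- positive_select(x, c(0.2, 0, -0.1))
  expect_equal(sel$indices, 1L)
  expect_equal(positive_select(x, c(1, 2, 3))$indices, 1:3)
  expect_error(positive_select(x, c(0, -1, 0)), "positive weight")
})

test_that("NCA upweights informative features on a planted toy", {
  toy <- make_planted_matrix(n_per_class = 10, n_classes = 3,
                             n_informative = 3, n_noise = 15)
  xn <- minmax_normalize(toy$x)
  w <- nca_weights(xn, toy$labels)
  expect_true(all(w >= 0))
  # the top-ranked feature is informative, and informative features carry
  # more total weight than the (five times more numerous) noise features
  expect_true(which.max(w) %in% toy$informative)
  expect_gt(sum(w[toy$informative]), sum(w[-toy$informative]))
  # determinism
  expect_identical(w, nca_weights(xn, toy$labels))
})

test_that("INCA evaluates every candidate size and picks the loss minimum", {
  toy <- make_planted_matrix(n_per_class = 12, n_classes = 3,
                             n_informative = 4, n_noise = 26)
  xn <- minmax_normalize(toy$x)
  sel <- inca_select(xn, toy$labels, kmin = 2, kmax = 20, folds = 3, seed = 1)
  expect_length(sel$loss_curve, 19)
  expect_equal(sel$candidate_k, 2:20)
  expect_equal(min(sel$loss_curve),
               sel$loss_curve[sel$chosen_k - 1])
  # smallest k on ties
  expect_equal(sel$chosen_k,
               sel$candidate_k[which(sel$loss_curve == min(sel$loss_curve))[1]])
  expect_length(sel$indices, sel$chosen_k)

  # degenerate single-candidate loop
  one <- inca_select(xn, toy$labels, kmin = 5, kmax = 5, folds = 3, seed = 1)
  expect_length(one$loss_curve, 1)
  expect_equal(one$chosen_k, 5)

  # clamping when fewer features than kmin survive
  expect_message(
    clamped <- inca_select(xn[, 1:8], toy$labels, kmin = 100, kmax = 1000,
                           folds = 3, seed = 1),
    "clamping")
  expect_equal(clamped$chosen_k, 8)
  expect_error(inca_select(xn[, 1:8], toy$labels, kmin = 100, clamp = FALSE),
               "kmin")
})

test_that("Gram-factor reformulation reproduces direct SVM cross-validation", {
  toy <- make_planted_matrix(n_per_class = 8, n_classes = 3,
                             n_informative = 3, n_noise = 10, seed = 5)
  xn <- minmax_normalize(toy$x)
  fold <- make_folds(toy$labels, 4, 9)
  direct <- ltetrolet:::.cv_error(xn, toy$labels, fold)
  factored <- ltetrolet:::.cv_error(ltetrolet:::.gram_factor(tcrossprod(xn)),
                                    toy$labels, fold)
  expect_equal(factored, direct)
})

test_that("full selector trace is nested and deterministic", {
  toy <- make_planted_matrix(n_per_class = 12, n_classes = 3,
                             n_informative = 4, n_noise = 25, seed = 3)
  x <- cbind(toy$x, 7)  # add one constant column for the threshold stage
  tr <- tsrfinca(x, toy$labels, kmin = 2, kmax = 15, folds = 3, seed = 2)
  expect_s3_class(tr, "ltp_selection_trace")
  expect_true(all(tr$final_indices %in% tr$kept_after_relieff))
  expect_true(all(tr$kept_after_relieff %in% tr$kept_after_threshold))
  expect_false(ncol(x) %in% tr$kept_after_threshold)  # constant column gone
  expect_true(tr$chosen_k >= 2 && tr$chosen_k <= 15)
  # the selected subset leans on planted features: the top-ranked surviving
  # feature is informative
  top <- tr$kept_after_relieff[tr$nca_weights == max(tr$nca_weights)][1]
  expect_true(top %in% toy$informative)

  tr2 <- tsrfinca(x, toy$labels, kmin = 2, kmax = 15, folds = 3, seed = 2)
  expect_identical(tr$final_indices, tr2$final_indices)
  expect_identical(tr$loss_curve, tr2$loss_curve)
})

test_that("selected subset beats a random subset of equal size", {
  toy <- make_planted_matrix(n_per_class = 12, n_classes = 3,
                             n_informative = 4, n_noise = 40, seed = 6)
  tr <- tsrfinca(toy$x, toy$labels, kmin = 4, kmax = 10, folds = 3, seed = 2)
  xn <- minmax_normalize(toy$x)
  fold <- make_folds(toy$labels, 3, 2)
  err_sel <- ltetrolet:::.cv_error(tr$x_selected, toy$labels, fold)
  err_rand <- mean(vapply(1:10, function(s) {
    cols <- withr::with_seed(s, sample(ncol(xn), tr$chosen_k))
    ltetrolet:::.cv_error(xn[, cols, drop = FALSE], toy$labels, fold)
  }, numeric(1)))
  expect_lte(err_sel, err_rand)
})
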