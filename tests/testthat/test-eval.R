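test_that("stratified folds are balanced, seeded and guarded", {
  y <- gl(6, 30)
  f <- make_folds(y, 10, seed = 4)
  expect_equal(sort(unique(f)), 1:10)
  for (cl in levels(y)) expect_equal(as.vector(table(f[y == cl])), rep(3L, 10))
  expect_identical(f, make_folds(y, 10, seed = 4))
  expect_false(identical(f, make_folds(y, 10, seed = 5)))
  expect_error(make_folds(gl(2, 4), 10), ">= 10")
})

test_that("confusion metrics reproduce hand-computed cases", {
  ident <- diag(10, 6)
  m <- metrics_from_confusion(ident)
  expect_equal(unname(m), rep(100, 6))

  m2 <- metrics_from_confusion(matrix(c(8, 1, 2, 9), 2))  # rows = true
  expect_equal(m2[["accuracy"]], 85)
  expect_equal(m2[["sensitivity"]], 85)
  expect_equal(m2[["geometric_mean"]], 100 * sqrt(0.8 * 0.9))
  expect_equal(m2[["specificity"]], 85)

  # everything predicted into class 1
  degen <- matrix(0, 3, 3); degen[, 1] <- 5
  expect_warning(m3 <- metrics_from_confusion(degen), "never predicted")
  expect_equal(m3[["accuracy"]], 100 / 3)
  expect_equal(m3[["geometric_mean"]], 0)
})

test_that("cross-validation separates a trivially separable six-class toy", {
  withr::with_seed(10, {
    y <- factor(rep(c("W", "S1", "S2", "S3", "S4", "REM"), each = 12))
    centers <- diag(6)[as.integer(y), ]
    x <- centers + matrix(rnorm(length(y) * 6, sd = 0.01), ncol = 6)
  })
  rep <- cross_validate(x, y, folds = 10, seed = 1)
  expect_s3_class(rep, "ltp_eval_report")
  expect_equal(rep$fold_accuracies, rep(100, 10))
  expect_equal(sum(rep$confusion), length(y))
  expect_equal(rep$metrics[["accuracy"]],
               100 * sum(diag(rep$confusion)) / sum(rep$confusion))
})

test_that("label-shuffled features score near chance", {
  withr::with_seed(20, {
    y <- gl(6, 15)
    x <- matrix(runif(90 * 30), 90)
    accs <- vapply(1:10, function(s) {
      ys <- withr::with_seed(s, sample(y))
      cross_validate(x, ys, folds = 3, seed = s)$metrics[["accuracy"]]
    }, numeric(1))
  })
  expect_lt(abs(mean(accs) - 100 / 6), 10)
})

test_that("mean fold accuracy tracks pooled accuracy on balanced data", {
  withr::with_seed(31, {
    y <- gl(6, 20)
    x <- diag(6)[as.integer(y), ] * 0.5 + matrix(rnorm(120 * 6, sd = 0.4), 120)
  })
  rep <- cross_validate(x, y, folds = 10, seed = 2)
  expect_lt(abs(mean(rep$fold_accuracies) - rep$metrics[["accuracy"]]), 1)
  # determinism of the full report
  rep2 <- cross_validate(x, y, folds = 10, seed = 2)
  expect_identical(rep, rep2)
})

test_that("classifier comparison harness covers the eight classifiers", {
  withr::with_seed(44, {
    y <- gl(6, 10)
    x <- diag(6)[as.integer(y), ] + matrix(rnorm(60 * 6, sd = 0.01), 60)
  })
  tab <- compare_classifiers(x, y, folds = 5, seed = 1)
  expect_equal(nrow(tab), 8)
  expect_true("CSVM" %in% tab$classifier)
  expect_equal(tab$accuracy[tab$classifier == "CSVM"], 100)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
})
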