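test_that("level block has the fixed 2192 layout", {
  withr::with_seed(21, {
    x <- rnorm(4096)
    lf <- level_features(x)
    expect_length(lf, 2192)
    # first signal block is the raw tetrolet histogram
    expect_equal(lf[1:512], tetrolet_features(x))
    expect_equal(lf[513:530], compute_moments(x))
    expect_equal(lf[531:548], compute_moments(tetrolet_features(x)))
    # second block is the average-pooled branch
    expect_equal(lf[549:1060], tetrolet_features(decompose_triple(x)$m1))
  })
  expect_error(level_features(rnorm(20)), "at least 32")
})

test_that("constant signal puts all histogram mass at code 255", {
  lf <- level_features(rep(0, 64))
  hist_mass <- lf[1:512]
  expect_equal(which(hist_mass > 0), c(256, 512))
})

test_that("epoch feature vector has 2192 x levels entries with halving levels", {
  withr::with_seed(33, {
    x <- rnorm(3840)  # 30 s at 128 Hz
    f5 <- extract_features(x)
    expect_length(f5, 10960)
    expect_length(extract_features(x, levels = 1), 2192)
    # level 1 block equals the single-level features of the raw signal
    expect_equal(f5[1:2192], level_features(x))
    # level 2 block starts from the max-pooled signal
    expect_equal(f5[2193:4384], level_features(max_pool(x)))
  })
  expect_error(extract_features(rnorm(511)), "at least 512")
  expect_error(extract_features(rnorm(100), levels = 3), "at least 128")
})

test_that("all textural coordinates are invariant under positive rescaling", {
  tex_idx <- rep(rep(c(TRUE, FALSE), c(512, 36)), 4 * 5)
  withr::with_seed(77, {
    x <- rnorm(512)
    f1 <- extract_features(x)
    f2 <- extract_features(0.035 * x)
    expect_length(which(tex_idx), 10240)
    expect_equal(f2[tex_idx], f1[tex_idx])
    expect_false(isTRUE(all.equal(f2[!tex_idx], f1[!tex_idx])))
  })
})

test_that("feature matrix persistence round-trips", {
  withr::with_seed(4, {
    epochs <- replicate(6, rnorm(512), simplify = FALSE)
    labels <- factor(c("W", "S1", "S2", "S3", "S4", "REM"))
    fm <- epoch_feature_matrix(epochs, labels, levels = 2)
    expect_equal(dim(fm$features), c(6, 4384))
    stem <- file.path(withr::local_tempdir(), "feat")
    write_feature_matrix(fm, stem, levels = 2)
    back <- read_feature_matrix(stem)
    expect_equal(unname(back$features), unname(fm$features), tolerance = 1e-12)
    expect_equal(as.character(back$labels), as.character(fm$labels))
    expect_equal(back$header$levels, 2)
  })
})
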