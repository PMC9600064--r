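test_that("EDF write/read round-trips within 16-bit quantization", {
  withr::with_seed(6, {
    fs <- 128
    sig <- list(F4 = rnorm(fs * 60), C4 = rnorm(fs * 60))
  })
  path <- file.path(withr::local_tempdir(), "rec.edf")
  write_edf(path, sig, fs = fs)
  back <- read_edf(path)
  expect_named(back$channels, c("F4", "C4"))
  expect_equal(unname(back$fs), c(fs, fs))
  quant <- (max(sig$F4) - min(sig$F4)) / 65535
  expect_lt(max(abs(back$channels$F4 - sig$F4)), quant)
  expect_lt(max(abs(back$channels$C4 - sig$C4)), quant)
})

test_that("stage label dialects are normalized and unknowns warned about", {
  expect_equal(
    normalize_stage_labels(c("Sleep stage 1", "N3", "w", "REM", "4")),
    c("S1", "S3", "W", "REM", "S4"))
  expect_warning(out <- normalize_stage_labels(c("W", "artifact")), "unknown")
  expect_equal(out, c("W", NA))
  expect_true(is.na(normalize_stage_labels("MT")))
})

test_that("epoch loader cuts annotation-aligned epochs and derives bipolar channels", {
  withr::with_seed(61, {
    fs <- 128
    n_sec <- 600  # 10 minutes
    f4 <- rnorm(fs * n_sec)
    c4 <- rnorm(fs * n_sec)
  })
  dir <- withr::local_tempdir()
  edf <- file.path(dir, "rec.edf")
  write_edf(edf, list(F4 = f4, C4 = c4), fs = fs)
  ann <- file.path(dir, "stages.txt")
  onsets <- seq(0, by = 30, length.out = 20)
  stages <- rep(c("W", "S1", "S2", "S3", "S4", "R", "MT"), length.out = 20)
  writeLines(paste(onsets, stages), ann)

  es <- load_edf_epochs(edf, ann, channel = "F4-C4")
  n_mt <- sum(stages == "MT")
  expect_length(es$epochs, 20 - n_mt)
  expect_true(all(lengths(es$epochs) == fs * 30))
  expect_false(any(is.na(es$labels)))
  # derived channel equals the samplewise difference up to quantization
  want <- (f4 - c4)[1:(fs * 30)]
  quant <- (diff(range(f4)) + diff(range(c4))) / 65535
  expect_lt(max(abs(es$epochs[[1]] - want)), quant)

  # requesting a recorded channel directly also works
  es2 <- load_edf_epochs(edf, ann, channel = "F4")
  expect_equal(length(es2$epochs), length(es$epochs))

  expect_error(load_edf_epochs(edf, ann, channel = "O1-O2"), "not found")

  # only-MT recording gives an empty set with a warning
  ann_mt <- file.path(dir, "mt.txt")
  writeLines(paste(c(0, 30), c("MT", "MT")), ann_mt)
  expect_warning(empty <- load_edf_epochs(edf, ann_mt), "no usable")
  expect_length(empty$epochs, 0)
})

test_that("synthetic epochs survive an EDF round-trip", {
  cfg <- synth_config(n_per_class = 1, seed = 12)
  x <- gen_epoch(cfg, "W", 1)
  dir <- withr::local_tempdir()
  edf <- file.path(dir, "synth.edf")
  write_edf(edf, list(`F4-C4` = x), fs = 128)
  ann <- file.path(dir, "ann.txt")
  writeLines("0 W", ann)
  es <- load_edf_epochs(edf, ann)
  expect_length(es$epochs, 1)
  quant <- diff(range(x)) / 65535
  expect_lt(max(abs(es$epochs[[1]] - x)), quant)
  expect_equal(as.character(es$labels), "W")
})
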