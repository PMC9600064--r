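# Seeded generator of balanced six-class synthetic EEG-like epoch datasets.
#
# Each sleep stage gets a fixed spectral profile (band-limited sinusoids
# with random phases) on top of 1/f colored noise, loosely following
# sleep-EEG physiology: alpha-dominated wake, theta in S1, spindle bursts
# in S2, slow delta in S3/S4 with growing amplitude, and a mixed
# theta + beta profile for REM. Epochs are deterministic functions of
# (seed, class, index), so any subset of a dataset can be regenerated.

.synth_stages <- c("W", "S1", "S2", "S3", "S4", "REM")

# Per-class spectral profiles: components as (frequency Hz, amplitude),
# burst_hz > 0 switches a component to 50%-duty amplitude-modulated bursts
# (sleep-spindle-like for S2).
.synth_profiles <- list(
  W   = list(comps = list(c(10, 1.0), c(20, 0.25))),
  S1  = list(comps = list(c(6, 0.8), c(10, 0.3))),
  S2  = list(comps = list(c(13, 1.0), c(3, 0.4)), burst_hz = 0.5),
  S3  = list(comps = list(c(2.5, 1.5), c(13, 0.2))),
  S4  = list(comps = list(c(1, 2.5))),
  REM = list(comps = list(c(5, 0.7), c(20, 0.45)))
)

#' Synthetic-dataset configuration
#'
#' @param sampling_rate Samples per second (default 128).
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @param n_per_class Epochs per sleep stage (default 50).
#' @param noise_amp Amplitude of the 1/f background noise (default 1).
#' @param seed Master seed; every epoch's samples are a pure function of
#'   (seed, class, index).
#' @return List of class `ltp_synth_config`. Epoch length
#'   `sampling_rate * epoch_seconds` must be >= 512 so the 5-level extractor
#'   applies.
#' @export
synth_config <- function(sampling_rate = 128, epoch_seconds = 30,
                         n_per_class = 50L, noise_amp = 1, seed = 1L) {
  len <- sampling_rate * epoch_seconds
  if (len < 512) {
    stop("epoch length ", len, " < 512 samples; increase sampling_rate or ",
         "epoch_seconds", call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate,
                 epoch_seconds = epoch_seconds,
                 n_per_class = as.integer(n_per_class),
                 noise_amp = noise_amp,
                 classes = .synth_stages,
                 seed = as.integer(seed)),
            class = "ltp_synth_config")
}

# Deterministic per-epoch substream seed, kept below 2^31.
.epoch_seed <- function(seed, class_id, index) {
  as.integer((as.double(seed) * 7919 + class_id * 104729 +
                index * 15485863) %% 2147483629)
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise.
.pink_noise <- function(n, fs) {
  spec <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) * fs / n          # two-sided frequency axis
  shaped <- spec / sqrt(pmax(f, fs / n))
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic epoch
#'
#' Sum of the stage's sinusoids with uniformly random phases plus 1/f
#' colored noise; deterministic given `(config$seed, class_id, index)`.
#'
#' @param config [synth_config()] object.
#' @param class_id Stage label (one of W, S1, S2, S3, S4, REM) or its index
#'   in 1..6.
#' @param index Epoch index within the class (>= 1).
#' @return Numeric vector of `sampling_rate * epoch_seconds` samples.
#' @export
gen_epoch <- function(config, class_id, index) {
  stopifnot(inherits(config, "ltp_synth_config"))
  if (is.character(class_id)) {
    ci <- match(class_id, config$classes)
    if (is.na(ci)) {
      stop("unknown class '", class_id, "'; expected one of ",
           paste(config$classes, collapse = ", "), call. = FALSE)
    }
  } else {
    ci <- as.integer(class_id)
    if (is.na(ci) || ci < 1L || ci > length(config$classes)) {
      stop("class index out of range 1..", length(config$classes),
           call. = FALSE)
    }
  }
  prof <- .synth_profiles[[config$classes[ci]]]
  n <- config$sampling_rate * config$epoch_seconds
  t <- seq(0, by = 1 / config$sampling_rate, length.out = n)

  .with_seed(.epoch_seed(config$seed, ci, index), {
    x <- numeric(n)
    for (comp in prof$comps) {
      phase <- stats::runif(1, 0, 2 * pi)
      wave <- comp[2] * sin(2 * pi * comp[1] * t + phase)
      if (!is.null(prof$burst_hz) && comp[1] > 5) {
        env_phase <- stats::runif(1, 0, 2 * pi)
        wave <- wave * as.numeric(sin(2 * pi * prof$burst_hz * t +
                                        env_phase) > 0)
      }
      x <- x + wave
    }
    if (config$noise_amp > 0) {
      x <- x + config$noise_amp * .pink_noise(n, config$sampling_rate)
    }
    x
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' @param config [synth_config()] object.
#' @return List with `epochs` (list of `6 * n_per_class` signals), `labels`
#'   (factor) and `config`; epoch order is shuffled deterministically under
#'   the config seed.
#' @export
gen_dataset <- function(config) {
  stopifnot(inherits(config, "ltp_synth_config"))
  grid <- expand.grid(index = seq_len(config$n_per_class),
                      class = seq_along(config$classes))
  epochs <- mapply(function(ci, idx) gen_epoch(config, ci, idx),
                   grid$class, grid$index, SIMPLIFY = FALSE)
  labels <- factor(config$classes[grid$class], levels = config$classes)
  perm <- .with_seed(config$seed, sample.int(nrow(grid)))
  list(epochs = epochs[perm], labels = labels[perm], config = config)
}
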