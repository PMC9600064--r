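# Multilevel feature extraction: at each level the current signal is
# decomposed into {raw, M1, M2, M3}, each contributing 512 textural + 18
# signal moments + 18 textural-vector moments = 548 features; the level
# block is 4 x 548 = 2192 features, and the signal is then halved by max
# pooling before the next level. Five levels give 10,960 features.
#
# Concatenation orders (within-signal, across signals, across levels) are a
# frozen package convention: selected-feature indices reported by the
# selector are only meaningful against this layout.

#' Single-level feature block of a signal
#'
#' For each of the four signals raw, M1 (average pooled), M2
#' (absolute-average pooled), M3 (absolute-maximum pooled), concatenates the
#' 512 L-tetrolet features, the 18 moments of the signal, and the 18 moments
#' of the 512-length textural vector, in that order. Signal order is raw,
#' M1, M2, M3.
#'
#' @param x Numeric vector of length >= 32 (so the pooled signals still host
#'   at least one 16-sample window).
#' @return Numeric vector of length 2192.
#' @export
level_features <- function(x) {
  .check_signal(x, min_len = 32L)
  triple <- decompose_triple(x)
  signals <- list(x, triple$m1, triple$m2, triple$m3)
  unlist(lapply(signals, function(s) {
    tf <- tetrolet_features(s)
    c(tf, compute_moments(s), compute_moments(tf))
  }), use.names = FALSE)
}

#' Multilevel epoch feature vector
#'
#' Runs [level_features()] on the signal, halves the signal with
#' [max_pool()], and repeats for `levels` levels, concatenating the level
#' blocks in level order. With the default 5 levels the output has
#' `2192 * 5 = 10960` entries. All `512 * 4 * levels` textural coordinates
#' are invariant under positive rescaling of the input.
#'
#' @param x Numeric vector; minimum length `32 * 2^(levels - 1)` (512 for 5
#'   levels), so every pooled branch at every level hosts a 16-sample
#'   window. A 30-s epoch at >= 100 Hz always qualifies.
#' @param levels Integer number of decomposition levels (default 5).
#' @return Numeric vector of length `2192 * levels`.
#' @examples
#' length(extract_features(rnorm(3840)))  # 10960
#' @export
extract_features <- function(x, levels = 5L) {
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  min_len <- 32L * 2L^(levels - 1L)
  if (length(x) < min_len) {
    stop(sprintf(
      "signal of length %d too short for %d levels; need at least %d samples",
      length(x), levels, min_len), call. = FALSE)
  }
  .check_signal(x, min_len = min_len)
  out <- vector("list", levels)
  cur <- x
  for (lev in seq_len(levels)) {
    stopifnot(length(cur) == length(x) %/% 2L^(lev - 1L))
    out[[lev]] <- level_features(cur)
    cur <- max_pool(cur)
  }
  unlist(out, use.names = FALSE)
}

#' Feature matrix of an epoch set
#'
#' Applies [extract_features()] to every epoch and stacks the results into
#' an observations x features matrix with the epoch labels attached.
#'
#' @param epochs List of numeric epoch signals.
#' @param labels Vector of stage labels, one per epoch (coerced to factor).
#' @param levels Number of decomposition levels (default 5).
#' @param verbose Print progress every 50 epochs.
#' @return List with `features` (numeric matrix, `2192 * levels` columns,
#'   column names `L<level>.<signal>.<block><index>`) and `labels` (factor).
#' @export
epoch_feature_matrix <- function(epochs, labels, levels = 5L, verbose = FALSE) {
  stopifnot(is.list(epochs), length(epochs) == length(labels))
  k <- 2192L * as.integer(levels)
  mat <- matrix(0, nrow = length(epochs), ncol = k)
  for (i in seq_along(epochs)) {
    mat[i, ] <- extract_features(epochs[[i]], levels = levels)
    if (verbose && i %% 50L == 0L) {
      message(sprintf("extracted %d / %d epochs", i, length(epochs)))
    }
  }
  colnames(mat) <- feature_layout_names(levels)
  list(features = mat, labels = factor(labels))
}

#' Canonical feature-layout column names
#'
#' @param levels Number of levels.
#' @return Character vector of `2192 * levels` names of the form
#'   `L<level>.<signal>.<block><index>` with signal in raw/m1/m2/m3 and
#'   block in tet (512), sig (18 signal moments), txm (18 textural moments).
#' @export
feature_layout_names <- function(levels = 5L) {
  per_signal <- c(paste0("tet", 1:512), paste0("sig", 1:18), paste0("txm", 1:18))
  per_level <- paste0(rep(c("raw", "m1", "m2", "m3"), each = 548L), ".",
                      per_signal)
  paste0("L", rep(seq_len(levels), each = 2192L), ".", per_level)
}

#' Persist a feature matrix to plain-text files
#'
#' Writes `<stem>_features.csv` (rectangular numeric table, one row per
#' epoch), `<stem>_labels.txt` (one label per line) and `<stem>_header.json`
#' (levels, layout version, dimensions, per-epoch provenance).
#'
#' @param fm List as returned by [epoch_feature_matrix()].
#' @param stem Output path stem.
#' @param levels Number of levels recorded in the header.
#' @param provenance Optional character vector (one entry per epoch).
#' @return Invisibly, the three file paths.
#' @export
write_feature_matrix <- function(fm, stem, levels = 5L, provenance = NULL) {
  paths <- c(features = paste0(stem, "_features.csv"),
             labels = paste0(stem, "_labels.txt"),
             header = paste0(stem, "_header.json"))
  data.table::fwrite(data.table::as.data.table(fm$features), paths[["features"]])
  writeLines(as.character(fm$labels), paths[["labels"]])
  hdr <- list(layout = "ltetrolet-v1", levels = as.integer(levels),
              n_epochs = nrow(fm$features), n_features = ncol(fm$features),
              classes = levels(fm$labels))
  if (!is.null(provenance)) hdr$provenance <- as.character(provenance)
  jsonlite::write_json(hdr, paths[["header"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Load a feature matrix written by [write_feature_matrix()]
#'
#' @param stem Path stem used when writing.
#' @return List with `features` (matrix), `labels` (factor) and `header`.
#' @export
read_feature_matrix <- function(stem) {
  feats <- as.matrix(data.table::fread(paste0(stem, "_features.csv")))
  hdr <- jsonlite::read_json(paste0(stem, "_header.json"), simplifyVector = TRUE)
  labs <- readLines(paste0(stem, "_labels.txt"))
  labs <- if (is.null(hdr$classes)) factor(labs) else
    factor(labs, levels = hdr$classes)
  if (nrow(feats) != length(labs)) {
    stop("feature matrix and label file disagree on epoch count", call. = FALSE)
  }
  list(features = feats, labels = labs, header = hdr)
}
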