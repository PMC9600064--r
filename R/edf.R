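# Minimal EDF (European Data Format) reader/writer and annotation-aligned
# epoch extraction.
#
# Covers the plain continuous-EDF subset used for polysomnography exports:
# ASCII headers, 16-bit little-endian samples, per-signal linear scaling
# between digital and physical ranges. Stage annotations come from a
# two-column text sidecar (onset_seconds, stage); one epoch is cut per
# annotated 30-s window, aligned to the annotation onset.

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a minimal EDF file
#'
#' @param path Output path.
#' @param channels Named list of equal-scale numeric vectors (one per
#'   channel); all channels share `fs` and must have equal length, a whole
#'   number of seconds.
#' @param fs Sampling rate in Hz (samples per 1-s data record).
#' @param patient,recording Header identification strings.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(path, channels, fs, patient = "X", recording = "synthetic") {
  stopifnot(is.list(channels), length(channels) > 0, !is.null(names(channels)))
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) stop("channels must have equal length")
  n_rec <- lens[[1]] %/% fs
  if (n_rec * fs != lens[[1]]) stop("signal length must be a whole number of 1-s records")
  ns <- length(channels)

  phys_min <- vapply(channels, min, numeric(1))
  phys_max <- vapply(channels, max, numeric(1))
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad(patient, 80), .pad(recording, 80),
    .pad("01.01.00", 8), .pad("00.00.00", 8),
    .pad(256 * (1 + ns), 8), .pad("", 44), .pad(n_rec, 8), .pad(1, 8),
    .pad(ns, 4))
  field <- function(vals, width) paste(vapply(vals, .pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(hdr,
    field(names(channels), 16), field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(sprintf("%g", phys_min), 8), field(sprintf("%g", phys_max), 8),
    field(rep(dig_min, ns), 8), field(rep(dig_max, ns), 8),
    field(rep("", ns), 80), field(rep(fs, ns), 8), field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)

  # digitize: linear map physical -> [-32768, 32767]
  dig <- lapply(seq_len(ns), function(j) {
    g <- (dig_max - dig_min) / (phys_max[j] - phys_min[j])
    as.integer(round((channels[[j]] - phys_min[j]) * g + dig_min))
  })
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) writeBin(dig[[j]][sel], con, size = 2L,
                                    endian = "little")
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' @param path EDF file path.
#' @return List with `channels` (named list of numeric vectors in physical
#'   units), `fs` (named numeric, per channel), `record_duration`,
#'   `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')",
                           call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16); fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))  # samples per record
  fields(32)

  raw_all <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                     signed = TRUE, endian = "little")
  chans <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  offs <- cumsum(c(0, spr))
  rec_len <- sum(spr)
  for (r in seq_len(n_rec)) {
    base <- (r - 1) * rec_len
    for (j in seq_len(ns)) {
      seg <- raw_all[(base + offs[j] + 1):(base + offs[j] + spr[j])]
      chans[[j]][((r - 1) * spr[j] + 1):(r * spr[j])] <- seg
    }
  }
  for (j in seq_len(ns)) {
    g <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
    chans[[j]] <- (chans[[j]] - dig_min[j]) * g + phys_min[j]
  }
  names(chans) <- labels
  list(channels = chans, fs = stats::setNames(spr / rec_dur, labels),
       record_duration = rec_dur, n_records = n_rec)
}

# Sleep-stage label dialects -> canonical six classes; MT maps to NA and is
# dropped by the loader.
.stage_map <- c(
  "W" = "W", "WAKE" = "W", "SLEEP STAGE W" = "W", "0" = "W",
  "S1" = "S1", "N1" = "S1", "1" = "S1", "SLEEP STAGE 1" = "S1",
  "S2" = "S2", "N2" = "S2", "2" = "S2", "SLEEP STAGE 2" = "S2",
  "S3" = "S3", "N3" = "S3", "3" = "S3", "SLEEP STAGE 3" = "S3",
  "S4" = "S4", "4" = "S4", "SLEEP STAGE 4" = "S4",
  "R" = "REM", "REM" = "REM", "SLEEP STAGE R" = "REM", "5" = "REM",
  "MT" = NA, "SLEEP STAGE ?" = NA)

normalize_stage_labels <- function(raw) {
  key <- toupper(trimws(raw))
  out <- .stage_map[key]
  unknown <- !(key %in% names(.stage_map))
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " annotation(s) with unknown stage ",
            "label(s): ", paste(unique(key[unknown]), collapse = ", "))
  }
  out[unknown] <- NA
  unname(out)
}

#' Load labeled 30-s epochs from an EDF recording
#'
#' Extracts the named channel (deriving a bipolar channel such as "F4-C4"
#' as the samplewise difference of its two referenced electrodes when the
#' derived label itself is absent), then cuts one non-overlapping epoch per
#' annotated stage, aligned to the annotation onset. Annotations are a
#' two-column whitespace-separated text sidecar: onset_seconds, stage.
#' Stage dialects ("Sleep stage 1", "N1", "S1", ...) are normalized; MT and
#' unknown labels are dropped with a warning. Epochs running past the end of
#' the recording are dropped.
#'
#' @param edf_path EDF file path.
#' @param annotation_path Sidecar path.
#' @param channel Channel label to extract (default "F4-C4").
#' @param epoch_seconds Epoch duration (default 30).
#' @return List with `epochs` (list of numeric vectors), `labels` (factor
#'   over the six stages), `fs`, and `onsets` (seconds).
#' @export
load_edf_epochs <- function(edf_path, annotation_path, channel = "F4-C4",
                            epoch_seconds = 30) {
  edf <- read_edf(edf_path)
  if (channel %in% names(edf$channels)) {
    sig <- edf$channels[[channel]]
    fs <- edf$fs[[channel]]
  } else if (grepl("-", channel, fixed = TRUE)) {
    parts <- strsplit(channel, "-", fixed = TRUE)[[1]]
    if (length(parts) == 2 && all(parts %in% names(edf$channels))) {
      if (edf$fs[[parts[1]]] != edf$fs[[parts[2]]]) {
        stop("cannot derive ", channel, ": sampling rates differ (",
             edf$fs[[parts[1]]], " vs ", edf$fs[[parts[2]]], " Hz)",
             call. = FALSE)
      }
      sig <- edf$channels[[parts[1]]] - edf$channels[[parts[2]]]
      fs <- edf$fs[[parts[1]]]
    } else {
      stop("channel '", channel, "' not found and not derivable; available: ",
           paste(names(edf$channels), collapse = ", "), call. = FALSE)
    }
  } else {
    stop("channel '", channel, "' not found; available: ",
         paste(names(edf$channels), collapse = ", "), call. = FALSE)
  }

  ann <- utils::read.table(annotation_path, header = FALSE,
                           col.names = c("onset", "stage"),
                           colClasses = c("numeric", "character"))
  stages <- normalize_stage_labels(ann$stage)
  keep <- !is.na(stages)
  n_samp <- round(epoch_seconds * fs)
  epochs <- list(); labels <- character(); onsets <- numeric()
  for (i in which(keep)) {
    start <- round(ann$onset[i] * fs) + 1
    end <- start + n_samp - 1
    if (end > length(sig)) next
    epochs[[length(epochs) + 1L]] <- sig[start:end]
    labels <- c(labels, stages[i])
    onsets <- c(onsets, ann$onset[i])
  }
  if (length(epochs) == 0L) warning("no usable labeled epochs found")
  list(epochs = epochs,
       labels = factor(labels, levels = .synth_stages),
       fs = fs, onsets = onsets)
}
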