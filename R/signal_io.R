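#' Raw single-channel recording
#'
#' Lightweight container for one channel of a polysomnography recording.
#'
#' @param samples Numeric vector of samples (microvolts).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel Channel label.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, channel = "EEG") {
  stopifnot(is.numeric(samples), length(samples) > 0, is.numeric(fs), fs > 0)
  if (!all(is.finite(samples))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         channel = as.character(channel)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> channel '%s': %d samples at %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Epoched recording with stage labels
#'
#' A matrix of fixed-length epochs (rows) with one stage label per epoch.
#'
#' @param epochs Numeric matrix, one epoch per row.
#' @param fs Sampling rate in Hz.
#' @param labels Stage labels, one per row (coerced with [stage_factor()]).
#' @return Object of class `epoched_recording`.
#' @export
epoched_recording <- function(epochs, fs, labels) {
  epochs <- as.matrix(epochs)
  if (nrow(epochs) != length(labels)) {
    stop("number of labels must equal number of epochs", call. = FALSE)
  }
  structure(
    list(epochs = epochs, fs = as.numeric(fs), labels = stage_factor(labels)),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %d epochs x %d samples at %g Hz\n",
              nrow(x$epochs), ncol(x$epochs), x$fs))
  print(table(x$labels))
  invisible(x)
}

# ---- EDF codec --------------------------------------------------------------
# Minimal European Data Format (EDF/EDF+, 16-bit) support: enough to read a
# named signal with its header sampling rate, to parse an EDF+ annotation
# channel, and to write single-channel test/demo files.

edf_read_header <- function(con) {
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) stop("truncated EDF header", call. = FALSE)
    s
  }
  version_raw <- readBin(con, "raw", 8)
  if (version_raw[1] == as.raw(255)) {
    stop("unsupported sample encoding: 24-bit BDF file", call. = FALSE)
  }
  version <- trimws(rawToChar(version_raw))
  if (!identical(version, "0")) {
    stop("unsupported sample encoding: not a 16-bit EDF file", call. = FALSE)
  }
  patient <- rd(80); recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_records <- as.integer(rd(8))
  record_duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- fld(16); transducer <- fld(80); phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80)
  n_samples <- as.integer(fld(8))
  fld(32) # per-signal reserved
  list(version = version, patient = patient, recording = recording,
       startdate = startdate, starttime = starttime,
       header_bytes = header_bytes, reserved = reserved,
       n_records = n_records, record_duration = record_duration, ns = ns,
       labels = labels, phys_dim = phys_dim,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, n_samples = n_samples)
}

#' Read one signal from an EDF/EDF+ file
#'
#' Reads the named channel from a 16-bit EDF or EDF+ file and converts its
#' digital values to physical units using the header calibration.
#'
#' @param path Path to an EDF/EDF+ file.
#' @param channel Channel label as stored in the EDF header (whitespace
#'   trimmed), e.g. `"EEG Fpz-Cz"`.
#' @return A [raw_recording()] with the channel's samples and the header
#'   sampling rate (samples per record / record duration).
#' @export
read_edf_signal <- function(path, channel) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- edf_read_header(con)
  idx <- which(h$labels == channel)
  if (length(idx) == 0) {
    stop("channel not found: '", channel, "' (available: ",
         paste(h$labels, collapse = ", "), ")", call. = FALSE)
  }
  idx <- idx[1]
  per_rec <- sum(h$n_samples)
  raw_all <- readBin(con, integer(), n = h$n_records * per_rec,
                     size = 2, signed = TRUE, endian = "little")
  n_rec <- length(raw_all) %/% per_rec
  offs <- c(0, cumsum(h$n_samples))
  take <- outer(offs[idx] + seq_len(h$n_samples[idx]),
                (seq_len(n_rec) - 1) * per_rec, `+`)
  dig <- raw_all[as.vector(take)]
  gain <- (h$phys_max[idx] - h$phys_min[idx]) / (h$dig_max[idx] - h$dig_min[idx])
  phys <- (dig - h$dig_min[idx]) * gain + h$phys_min[idx]
  fs <- h$n_samples[idx] / h$record_duration
  raw_recording(phys, fs = fs, channel = channel)
}

#' Write a single-channel EDF file
#'
#' Writes one signal as a 16-bit EDF file with 1-second data records. Mainly
#' used by the `simulate` pipeline command and the test suite; any trailing
#' partial second is dropped.
#'
#' @param path Output path.
#' @param samples Numeric vector (microvolts).
#' @param fs Sampling rate in Hz (integer-valued).
#' @param channel Channel label to store.
#' @param phys_dim Physical dimension label.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, samples, fs, channel = "EEG Fpz-Cz",
                      phys_dim = "uV") {
  stopifnot(fs == round(fs), fs > 0)
  n_rec <- length(samples) %/% fs
  samples <- samples[seq_len(n_rec * fs)]
  pmin_ <- min(samples); pmax_ <- max(samples)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(round((samples - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  # numeric header fields are fixed 8-byte ASCII; shrink precision to fit
  num8 <- function(v) {
    for (d in 7:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    stop("value does not fit an 8-byte EDF header field", call. = FALSE)
  }
  rng <- pmax_ - pmin_
  pmin_ <- as.numeric(num8(pmin_ - 0.001 * rng))
  pmax_ <- as.numeric(num8(pmax_ + 0.001 * rng))
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dig <- as.integer(round((samples - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))
  dig <- as.integer(pmin(pmax(dig, dmin), dmax))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(256 + 256, 8),
    pad("", 44), pad(n_rec, 8), pad(1, 8), pad(1, 4),
    # one signal block
    pad(channel, 16), pad("", 80), pad(phys_dim, 8),
    pad(num8(pmin_), 8), pad(num8(pmax_), 8),
    pad(dmin, 8), pad(dmax, 8), pad("", 80), pad(fs, 8), pad("", 32)
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a hypnogram (stage annotation) file
#'
#' Accepts either an EDF+ file containing an `"EDF Annotations"` signal
#' (time-stamped annotation lists) or a plain-text fallback: a tab-separated
#' file with columns `onset`, `duration`, `label` (header required; `onset_s`
#' / `duration_s` also accepted). Intervals are returned sorted by onset and
#' must not overlap.
#'
#' @param path Path to an EDF+ annotation file or TSV hypnogram.
#' @return Tibble with columns `onset`, `duration` (seconds) and `label`
#'   (raw annotation text, e.g. `"Sleep stage W"`).
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  head8 <- readBin(con, "raw", 8)
  close(con)
  is_edf <- length(head8) == 8 && identical(trimws(rawToChar(head8)), "0")
  out <- if (is_edf) read_hypnogram_edf(path) else read_hypnogram_tsv(path)
  out <- dplyr::arrange(out, .data$onset)
  if (nrow(out) > 1) {
    gap <- out$onset[-1] - (out$onset[-nrow(out)] + out$duration[-nrow(out)])
    if (any(gap < -1e-9)) {
      stop("malformed hypnogram: overlapping annotation intervals",
           call. = FALSE)
    }
  }
  out
}

read_hypnogram_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  names(df) <- sub("_s$", "", tolower(names(df)))
  need <- c("onset", "duration", "label")
  if (!all(need %in% names(df))) {
    stop("malformed hypnogram: expected tab-separated columns ",
         "onset, duration, label", call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(tibble(onset = numeric(0), duration = numeric(0),
                  label = character(0)))
  }
  if (any(is.na(df$onset)) || any(is.na(df$duration))) {
    stop("malformed hypnogram: non-numeric onset/duration", call. = FALSE)
  }
  tibble(onset = as.numeric(df$onset), duration = as.numeric(df$duration),
         label = as.character(df$label))
}

read_hypnogram_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- edf_read_header(con)
  idx <- which(h$labels == "EDF Annotations")
  if (length(idx) == 0) {
    stop("no 'EDF Annotations' signal in EDF+ file", call. = FALSE)
  }
  idx <- idx[1]
  per_rec <- sum(h$n_samples)
  raw_all <- readBin(con, "raw", n = 2 * h$n_records * per_rec)
  offs <- 2 * c(0, cumsum(h$n_samples))
  res <- list()
  n_rec <- length(raw_all) %/% (2 * per_rec)
  for (r in seq_len(n_rec)) {
    a <- (r - 1) * 2 * per_rec + offs[idx] + 1
    b <- a + 2 * h$n_samples[idx] - 1
    res <- c(res, parse_tal_chunk(raw_all[a:b]))
  }
  if (length(res) == 0) {
    return(tibble(onset = numeric(0), duration = numeric(0),
                  label = character(0)))
  }
  dplyr::bind_rows(res)
}

# Parse one record's annotation bytes. Each time-stamped annotation list
# (TAL) is "onset[\x15duration]\x14text\x14...\x00"; TALs with no text are
# record timestamps and are skipped.
parse_tal_chunk <- function(bytes) {
  ends <- which(bytes == as.raw(0))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  for (i in seq_along(ends)) {
    if (starts[i] >= ends[i]) next
    tal <- rawToChar(bytes[starts[i]:(ends[i] - 1L)])
    fields <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(fields) < 2) next
    timing <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    if (is.na(suppressWarnings(as.numeric(timing[1])))) {
      stop("malformed annotation record in EDF+ file", call. = FALSE)
    }
    for (label in fields[-1]) {
      if (!nzchar(label)) next
      out[[length(out) + 1]] <- tibble(
        onset = as.numeric(timing[1]),
        duration = if (length(timing) >= 2) as.numeric(timing[2]) else 0,
        label = label
      )
    }
  }
  out
}

# ---- label mapping and epoching --------------------------------------------

#' Map raw hypnogram labels to AASM stages
#'
#' Maps Sleep-EDF style annotation vocabulary to the five AASM stages.
#' R&K stages 3 and 4 both map to N3; movement time and unscored epochs map
#' to `"drop"` and are discarded during epoching.
#'
#' @param raw_label Character vector of raw annotation labels (e.g.
#'   `"Sleep stage W"`, `"Sleep stage 4"`, `"Movement time"`, or the bare
#'   forms `"W"`, `"1"`, ..., `"R"`).
#' @return Character vector over `c(sleep_stages(), "drop")`.
#' @export
#' @examples
#' map_stage_labels(c("Sleep stage W", "Sleep stage 4", "Movement time"))
map_stage_labels <- function(raw_label) {
  key <- sub("^Sleep stage ", "", as.character(raw_label))
  lut <- c("W" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3",
           "R" = "REM", "Movement" = "drop", "Movement time" = "drop",
           "?" = "drop")
  out <- lut[key]
  if (any(is.na(out) & !is.na(key))) {
    stop("unknown hypnogram label(s): ",
         paste(unique(raw_label[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Cut a labelled recording into fixed 30-second epochs
#'
#' Epochs are consecutive non-overlapping windows of `epoch_s` seconds
#' anchored at the start of the recording. An epoch is kept only when it lies
#' entirely inside a single annotation interval whose label maps to one of
#' the five stages; epochs straddling a label boundary, falling in a
#' `"drop"` interval, or extending past the recording are discarded.
#'
#' @param rec A [raw_recording()].
#' @param intervals Tibble with columns `onset`, `duration`, `label` as
#'   returned by [read_hypnogram()].
#' @param epoch_s Epoch length in seconds (default 30; `fs * epoch_s` must be
#'   a whole number of samples).
#' @return An [epoched_recording()]; may contain zero epochs.
#' @export
make_epochs <- function(rec, intervals, epoch_s = 30) {
  stopifnot(inherits(rec, "raw_recording"))
  n_per <- rec$fs * epoch_s
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop("fs * epoch_s must be an integer number of samples", call. = FALSE)
  }
  n_per <- as.integer(round(n_per))
  n_win <- length(rec$samples) %/% n_per
  if (n_win == 0 || nrow(intervals) == 0) {
    return(epoched_recording(matrix(numeric(0), 0, n_per), rec$fs,
                             character(0)))
  }
  stage <- map_stage_labels(intervals$label)
  keep_rows <- integer(0); keep_lab <- character(0)
  for (w in seq_len(n_win)) {
    t0 <- (w - 1) * epoch_s; t1 <- w * epoch_s
    inside <- which(intervals$onset <= t0 + 1e-9 &
                      intervals$onset + intervals$duration >= t1 - 1e-9)
    if (length(inside) != 1) next
    if (stage[inside] == "drop") next
    keep_rows <- c(keep_rows, w)
    keep_lab <- c(keep_lab, stage[inside])
  }
  if (length(keep_rows) == 0) {
    return(epoched_recording(matrix(numeric(0), 0, n_per), rec$fs,
                             character(0)))
  }
  ep <- t(vapply(keep_rows, function(w) {
    rec$samples[((w - 1) * n_per + 1):(w * n_per)]
  }, numeric(n_per)))
  epoched_recording(ep, rec$fs, keep_lab)
}

#' Balance stage classes by seeded undersampling
#'
#' Draws, per stage, a uniform random subsample without replacement of the
#' requested size, then shuffles the pooled result. Fully reproducible under
#' `seed`.
#'
#' @param er An [epoched_recording()].
#' @param counts Named integer vector of requested per-stage counts (names
#'   from [sleep_stages()]; stages absent from `counts` are dropped).
#' @param seed Integer seed.
#' @return An [epoched_recording()] whose label histogram equals `counts`.
#' @export
balance_classes <- function(er, counts, seed = 1) {
  stopifnot(inherits(er, "epoched_recording"))
  counts <- counts[intersect(names(counts), sleep_stages())]
  withr::with_seed(seed, {
    idx <- unlist(lapply(names(counts), function(st) {
      pool <- which(er$labels == st)
      if (length(pool) < counts[[st]]) {
        stop("insufficient epochs for stage ", st, ": have ", length(pool),
             ", need ", counts[[st]], call. = FALSE)
      }
      pool[sample.int(length(pool), counts[[st]])]
    }))
    idx <- idx[sample.int(length(idx))]
  })
  epoched_recording(er$epochs[idx, , drop = FALSE], er$fs,
                    as.character(er$labels[idx]))
}
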