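# Shared fixtures, all generated in code at test time.

make_sine <- function(freq, fs = 100, n = 3000, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# Small stage-labelled synthetic feature table, computed once per session.
.fixture_env <- new.env(parent = emptyenv())

small_feature_table <- function(n_per_stage = 30, seed = 401) {
  key <- paste0("ft_", n_per_stage, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    ds <- generate_dataset(
      stats::setNames(rep(n_per_stage, 5), sleep_stages()),
      synthetic_recipe(), seed = seed
    )
    .fixture_env[[key]] <- extract_features(ds)
  }
  .fixture_env[[key]]
}

# Two well-separated Gaussian blobs in 4 dimensions, labelled with two
# stages so the classifier surface can be exercised cheaply.
blob_table <- function(n = 60, gap = 4, seed = 7) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * 4), ncol = 4),
               matrix(rnorm(n * 4, mean = gap), ncol = 4))
  })
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- paste0("V", 1:4)
  dplyr::bind_cols(
    tibble::tibble(stage = stage_factor(rep(c("W", "N3"), each = n))), out
  )
}

# Minimal EDF+ file holding only an "EDF Annotations" signal with the
# given intervals, built byte-by-byte (TALs separated by NUL).
write_edfplus_annotations <- function(path, onset, duration, label) {
  tal <- vapply(seq_along(onset), function(i) {
    paste0("+", format(onset[i]), "\x15", format(duration[i]), "\x14",
           label[i], "\x14\x01")
  }, character(1))
  payload <- paste0("+0\x14\x14\x01", paste(tal, collapse = ""))
  bytes <- charToRaw(payload)
  bytes[bytes == as.raw(1)] <- as.raw(0) # placeholder -> TAL terminator
  n_samp <- ceiling((length(bytes) + 1) / 2)
  bytes <- c(bytes, raw(2 * n_samp - length(bytes)))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X", 80), pad("X", 80), pad("01.01.00", 8),
    pad("00.00.00", 8), pad(512, 8), pad("EDF+C", 44), pad(1, 8),
    pad(1, 8), pad(1, 4),
    pad("EDF Annotations", 16), pad("", 80), pad("", 8), pad(-1, 8),
    pad(1, 8), pad(-32768, 8), pad(32767, 8), pad("", 80),
    pad(n_samp, 8), pad("", 32)
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(bytes, con)
  invisible(path)
}
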