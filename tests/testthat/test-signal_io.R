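test_that("EDF write/read round-trips a signal within quantization", {
  path <- withr::local_tempfile(fileext = ".edf")
  x <- make_sine(10, n = 6000, amp = 50)
  write_edf(path, x, fs = 100, channel = "EEG Fpz-Cz")
  rec <- read_edf_signal(path, "EEG Fpz-Cz")
  expect_s3_class(rec, "raw_recording")
  expect_equal(rec$fs, 100)
  expect_length(rec$samples, 6000)
  quant <- (max(x) - min(x)) / 65535
  expect_lt(max(abs(rec$samples - x)), 2 * quant)
})

test_that("EDF reader handles zeros and raises distinct errors", {
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(path, numeric(6000), fs = 100, channel = "EEG Fpz-Cz")
  rec <- read_edf_signal(path, "EEG Fpz-Cz")
  expect_length(rec$samples, 6000)
  expect_true(all(abs(rec$samples) < 1e-4))

  expect_error(read_edf_signal(path, "EOG"), "channel not found")
  expect_error(read_edf_signal(file.path(tempdir(), "nope.edf"), "EEG"),
               "file not found")
  bdf <- withr::local_tempfile(fileext = ".bdf")
  writeBin(c(as.raw(255), charToRaw("BIOSEMI")), bdf)
  expect_error(read_edf_signal(bdf, "EEG"), "unsupported sample encoding")
})

test_that("TSV hypnogram parsing orders intervals and rejects overlap", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\tlabel",
               "1800\t1800\tSleep stage 1",
               "0\t1800\tSleep stage W"), path)
  hyp <- read_hypnogram(path)
  expect_equal(hyp$onset, c(0, 1800))
  expect_equal(hyp$label, c("Sleep stage W", "Sleep stage 1"))

  writeLines("onset\tduration\tlabel", path)
  expect_equal(nrow(read_hypnogram(path)), 0)

  writeLines(c("onset\tduration\tlabel",
               "0\t1800\tSleep stage W",
               "900\t1800\tSleep stage 1"), path)
  expect_error(read_hypnogram(path), "overlap")
})

test_that("EDF+ annotation channel is parsed into intervals", {
  path <- withr::local_tempfile(fileext = ".edf")
  write_edfplus_annotations(path, onset = c(0, 1800),
                            duration = c(1800, 600),
                            label = c("Sleep stage W", "Sleep stage 2"))
  hyp <- read_hypnogram(path)
  expect_equal(nrow(hyp), 2)
  expect_equal(hyp$onset, c(0, 1800))
  expect_equal(hyp$duration, c(1800, 600))
  expect_equal(hyp$label, c("Sleep stage W", "Sleep stage 2"))
})

test_that("label mapping covers the annotation vocabulary", {
  expect_equal(map_stage_labels("Sleep stage 4"), "N3")
  expect_equal(map_stage_labels("Sleep stage 3"), "N3")
  expect_equal(map_stage_labels("Sleep stage R"), "REM")
  expect_equal(
    map_stage_labels(c("Sleep stage W", "Sleep stage 1", "Sleep stage 2",
                       "Movement time", "Sleep stage ?")),
    c("W", "N1", "N2", "drop", "drop")
  )
  expect_error(map_stage_labels("Sleep stage X"), "unknown")
  # surjective onto the five stages plus drop
  vocab <- c("Sleep stage W", "Sleep stage 1", "Sleep stage 2",
             "Sleep stage 3", "Sleep stage 4", "Sleep stage R",
             "Movement time")
  expect_setequal(map_stage_labels(vocab), c(sleep_stages(), "drop"))
})

test_that("epoching keeps only whole single-label windows", {
  iv <- function(onset, duration, label) {
    tibble::tibble(onset = onset, duration = duration, label = label)
  }
  rec <- raw_recording(seq_len(9000), fs = 100)
  er <- make_epochs(rec, iv(0, 90, "Sleep stage W"))
  expect_equal(nrow(er$epochs), 3)
  expect_equal(as.character(unique(er$labels)), "W")
  # epoch rows, concatenated, reproduce the used signal prefix exactly
  expect_identical(as.vector(t(er$epochs)), as.numeric(seq_len(9000)))

  er <- make_epochs(raw_recording(seq_len(4500), 100),
                    iv(0, 45, "Sleep stage W"))
  expect_equal(nrow(er$epochs), 1)

  er <- make_epochs(raw_recording(seq_len(6000), 100),
                    iv(c(0, 45), c(45, 15),
                       c("Sleep stage W", "Sleep stage 1")))
  expect_equal(nrow(er$epochs), 1)
  expect_equal(as.character(er$labels), "W")

  er <- make_epochs(raw_recording(seq_len(6000), 100),
                    iv(c(0, 30), c(30, 30),
                       c("Movement time", "Sleep stage R")))
  expect_equal(as.character(er$labels), "REM")
})

test_that("class balancing reproduces requested counts deterministically", {
  set.seed(11)
  n <- c(W = 12, N1 = 9, N2 = 10, N3 = 8, REM = 11)
  mat <- matrix(rnorm(50 * sum(n)), nrow = sum(n))
  er <- epoched_recording(mat, 100, rep(names(n), times = n))
  want <- c(W = 5, N1 = 5, N2 = 5, N3 = 4, REM = 5)
  bal <- balance_classes(er, want, seed = 3)
  expect_equal(as.vector(table(bal$labels)[names(want)]),
               unname(want), ignore_attr = TRUE)
  bal2 <- balance_classes(er, want, seed = 3)
  expect_identical(bal$epochs, bal2$epochs)
  expect_identical(bal$labels, bal2$labels)
  expect_error(balance_classes(er, c(W = 100), seed = 1), "insufficient")
})
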