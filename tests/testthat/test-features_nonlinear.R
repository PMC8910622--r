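test_that("Higuchi dimension hits the line and white-noise limits", {
  expect_equal(higuchi_fd(as.numeric(1:3000)), 1, tolerance = 0.01)
  fds <- vapply(1:20, function(i) {
    withr::with_seed(900 + i, higuchi_fd(rnorm(3000)))
  }, numeric(1))
  expect_equal(mean(fds), 2, tolerance = 0.1)
  cst <- higuchi_fd(rep(1, 3000))
  expect_equal(as.numeric(cst), 0)
  expect_true(attr(cst, "flagged"))
})

test_that("Higuchi dimension matches an lm-based oracle and rises with noise", {
  for (i in 1:5) {
    withr::with_seed(950 + i, x <- rnorm(400))
    expect_equal(higuchi_fd(x), oracle_higuchi(x), tolerance = 1e-9)
  }
  # the sine period (5 s at 0.2 Hz) must exceed the largest lag k_max so
  # the noise-free signal looks smooth at every lag
  mix_fd <- function(w, seed) {
    withr::with_seed(seed, e <- rnorm(3000))
    higuchi_fd((1 - w) * make_sine(0.2) * sqrt(2) + w * e)
  }
  fd <- vapply(c(0, 0.5, 1), function(w) {
    mean(vapply(1:5, function(s) mix_fd(w, 1000 + s), numeric(1)))
  }, numeric(1))
  expect_true(fd[1] < fd[2] && fd[2] < fd[3])
  expect_lt(fd[1], 1.3)
  expect_gt(fd[3], 1.9)
})

test_that("non-stationary index matches the segmentation oracle", {
  expect_equal(nsi(rep(3, 100)), 0)
  # N = 20, m = 3: segments of lengths 7, 7, 6
  x <- c(rep(0, 10), rep(2, 10))
  expect_equal(nsi(x), oracle_nsi(x))
  means <- c(0, mean(c(rep(0, 3), rep(2, 4))), 2)
  expect_equal(nsi(x), sqrt(mean((means - mean(means))^2)))
  for (i in 1:50) {
    withr::with_seed(1100 + i, x <- rnorm(300))
    expect_equal(nsi(x), oracle_nsi(x), tolerance = 1e-12)
  }
})

test_that("non-stationary index is affine-equivariant", {
  withr::with_seed(31, x <- rnorm(500))
  expect_equal(nsi(x + 100), nsi(x), tolerance = 1e-9)
  expect_equal(nsi(-2.5 * x), 2.5 * nsi(x), tolerance = 1e-9)
})

test_that("sample entropy is zero for periodic signals, matches the oracle", {
  p <- rep(c(1, 2, 3), 1000)
  expect_equal(as.numeric(sample_entropy(p)), 0, tolerance = 1e-12)
  for (i in 1:100) {
    withr::with_seed(1200 + i, x <- rnorm(300))
    expect_equal(as.numeric(sample_entropy(x)), oracle_sampen(x),
                 tolerance = 1e-12)
  }
  withr::with_seed(77, x <- rnorm(500))
  expect_equal(as.numeric(sample_entropy(x)), oracle_sampen(x),
               tolerance = 1e-12)
  cst <- sample_entropy(rep(1, 100))
  expect_true(is.na(cst))
  expect_true(attr(cst, "flagged"))
})

test_that("sample entropy is invariant under affine transforms", {
  withr::with_seed(41, x <- rnorm(400))
  expect_equal(as.numeric(sample_entropy(3 * x - 7)),
               as.numeric(sample_entropy(x)), tolerance = 1e-12)
})

test_that("nonlinear features are stable under time reversal", {
  # the strided/segmented estimators anchor at the start of the epoch, so
  # reversal changes which trailing samples fall off: equality is up to
  # those boundary terms, not exact
  withr::with_seed(51, x <- rnorm(600))
  xr <- rev(x)
  expect_equal(as.numeric(sample_entropy(xr)),
               as.numeric(sample_entropy(x)), tolerance = 0.02)
  expect_equal(nsi(xr), nsi(x), tolerance = 0.1)
  expect_equal(higuchi_fd(xr), higuchi_fd(x), tolerance = 0.02)
})
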