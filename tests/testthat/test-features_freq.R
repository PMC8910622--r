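test_that("periodogram concentrates an integer-period sinusoid", {
  x <- make_sine(10)
  ps <- power_spectrum(x, nfft = 3000, fs = 100)
  ac <- ps$power[ps$freq > 0]
  expect_gt(ps$power[ps$freq == 10] / sum(ac), 0.99)

  z <- power_spectrum(numeric(3000), fs = 100)
  expect_true(all(z$power == 0))
  expect_error(power_spectrum(numeric(3000), nfft = 1000), "nfft")
})

test_that("band powers match a direct two-sided DFT oracle", {
  sch <- band_scheme()
  for (i in 1:100) {
    withr::with_seed(500 + i, x <- rnorm(250))
    ps <- power_spectrum(x, fs = 100)
    E <- band_powers(ps, sch)
    want <- vapply(seq_len(nrow(sch)), function(b) {
      oracle_band_power(x, sch$low[b], sch$high[b], fs = 100)
    }, numeric(1))
    expect_equal(unname(E[2:8]), want, tolerance = 1e-9)
    expect_equal(unname(E["E1"]), oracle_band_power(x, 0.5, 45, 100),
                 tolerance = 1e-9)
    expect_equal(unname(E["E9"]), sum(want), tolerance = 1e-9)
  }
})

test_that("band powers reflect spectral content", {
  E <- band_powers(power_spectrum(make_sine(10), fs = 100))
  expect_gt(E["E5"] / E["E1"], 0.99)
  others <- E[c("E2", "E3", "E4", "E6", "E7", "E8")] / E[["E1"]]
  expect_true(all(others <= 0.01))
  expect_true(all(band_powers(power_spectrum(numeric(3000), fs = 100)) == 0))

  # flat white-noise spectrum: theta share ~ bandwidth share
  shares <- vapply(1:100, function(i) {
    withr::with_seed(600 + i, x <- rnorm(3000))
    E <- band_powers(power_spectrum(x, fs = 100))
    E[["E4"]] / E[["E1"]]
  }, numeric(1))
  expect_equal(mean(shares), 4 / 44.5, tolerance = 0.02)
})

test_that("tabulated ratio features follow their printed expressions", {
  E <- c(E1 = 3.5, E2 = 1, E3 = 1, E4 = 1, E5 = 1, E6 = 1, E7 = 1,
         E8 = 1, E9 = 7)
  f <- ratio_features(E)
  expect_equal(unname(f[c("F7", "F8", "F9", "F10", "F12")]),
               rep(1 / 3.5, 5))
  expect_equal(unname(f["F22"]), 2 / 7)
  expect_equal(unname(f["F23"]), 1)
  expect_equal(unname(f["F24"]), 2)
  expect_equal(unname(f["F2"]), 2)
  expect_equal(unname(f["F5"]), 2)

  zed <- ratio_features(c(E1 = 0, E2 = 0, E3 = 0, E4 = 0, E5 = 0,
                          E6 = 0, E7 = 0, E8 = 0, E9 = 0))
  expect_true(all(zed == 0))
  expect_true(attr(zed, "flagged"))
})

test_that("the shared-denominator identity F13 = F9 + F10 holds", {
  for (i in 1:20) {
    withr::with_seed(700 + i, x <- rnorm(500))
    E <- band_powers(power_spectrum(x, fs = 100))
    f <- ratio_features(E)
    expect_equal(unname(f["F13"]), unname(f["F9"] + f["F10"]),
                 tolerance = 1e-12)
  }
})

test_that("spectral moments recover point and two-point spectra", {
  f <- mpf_fv_features(power_spectrum(make_sine(10), fs = 100))
  expect_equal(unname(f["F26"]), 10, tolerance = 0.05) # full-band MPF
  expect_equal(unname(f["F33"]), 0, tolerance = 0.05)  # full-band FV
  expect_equal(unname(f["F30"]), 10, tolerance = 0.05) # alpha MPF

  two <- tibble::tibble(freq = c(8, 12), power = c(1, 1))
  f2 <- mpf_fv_features(two)
  expect_equal(unname(f2["F30"]), 10) # alpha-band MPF
  expect_equal(unname(f2["F37"]), 4)  # alpha-band FV
  expect_true(attr(f2, "flagged"))    # the empty bands are flagged zeros
  expect_equal(unname(f2["F29"]), 0)
})

test_that("ratio and moment features are amplitude-scale invariant", {
  for (i in 1:20) {
    withr::with_seed(800 + i, x <- rnorm(600))
    f1 <- freq_features(x, fs = 100)
    f2 <- freq_features(5.5 * x, fs = 100)
    ratios <- paste0("F", 7:39)
    expect_equal(f2[ratios], f1[ratios], tolerance = 1e-9)
  }
})
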