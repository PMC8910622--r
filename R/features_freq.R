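# Frequency-domain features F1-F39: periodogram, seven EEG rhythm band
# powers E1-E9, the tabulated power-ratio features, and power-weighted
# spectral moments (mean power frequency and frequency variance) per band.

#' The seven EEG rhythm bands
#'
#' Half-open frequency intervals `[low, high)` in Hz. The two delta bands
#' deliberately overlap on 1.2-2 Hz (the scheme distinguishes a low-delta
#' 0.5-2 Hz band and a high-delta 1.2-4 Hz band).
#'
#' @return Tibble with columns `band`, `low`, `high`.
#' @export
band_scheme <- function() {
  tibble(
    band = c("low_delta", "high_delta", "theta", "alpha",
             "low_beta", "high_beta", "gamma"),
    low = c(0.5, 1.2, 4, 8, 13, 20, 30),
    high = c(2, 4, 8, 13, 20, 30, 45)
  )
}

#' One-sided periodogram of an epoch
#'
#' Power at bin `k` is `|DFT(x)[k] / nfft|^2` for `k = 0..nfft/2`,
#' rectangular window, no zero-padding by default, and no one-sided
#' doubling; every downstream feature is a ratio or band-restricted moment,
#' so the absolute normalization cancels where it matters.
#'
#' @param epoch Numeric vector of samples.
#' @param nfft Transform length, at least `length(epoch)`.
#' @param fs Sampling rate in Hz.
#' @return Tibble with columns `freq` (Hz) and `power`, with attributes
#'   `nfft` and `fs`.
#' @export
power_spectrum <- function(epoch, nfft = length(epoch), fs = 100) {
  if (nfft < length(epoch)) {
    stop("nfft must be at least the epoch length", call. = FALSE)
  }
  x <- c(epoch, numeric(nfft - length(epoch)))
  X <- fft(x)
  half <- floor(nfft / 2)
  ps <- tibble(
    freq = (0:half) * fs / nfft,
    power = Mod(X[1:(half + 1)] / nfft)^2
  )
  attr(ps, "nfft") <- nfft
  attr(ps, "fs") <- fs
  ps
}

#' Band powers E1-E9
#'
#' `E1` is the total power over 0.5-45 Hz (the filtered support); `E2`-`E8`
#' are the seven rhythm-band powers in [band_scheme()] order (low-delta,
#' high-delta, theta, alpha, low-beta, high-beta, gamma), each summed over
#' bins with `low <= freq < high`; `E9 = E2 + ... + E8` (the overlapping
#' delta bands are double-counted there, by construction).
#'
#' @param ps Spectrum from [power_spectrum()].
#' @param scheme Band table as in [band_scheme()].
#' @return Named numeric vector `E1`...`E9`.
#' @export
band_powers <- function(ps, scheme = band_scheme()) {
  band_sum <- function(lo, hi) sum(ps$power[ps$freq >= lo & ps$freq < hi])
  e <- purrr::map2_dbl(scheme$low, scheme$high, band_sum)
  out <- c(band_sum(0.5, 45), e, sum(e))
  names(out) <- paste0("E", 1:9)
  out
}

safe_ratio <- function(num, den) if (den > 0) num / den else 0

#' Band-power combination and ratio features F1-F25
#'
#' The tabulated combinations of `E1`-`E9`: raw band powers and sums
#' (F1-F6) and nineteen power ratios (F7-F25). A ratio with a zero
#' denominator is reported as 0 and flagged.
#'
#' @param E Named vector from [band_powers()].
#' @return Named numeric vector `F1`...`F25` (flagged if any denominator
#'   was zero).
#' @export
ratio_features <- function(E) {
  e <- as.list(E)
  vals <- c(
    F1 = E[["E1"]],
    F2 = E[["E2"]] + E[["E3"]],
    F3 = E[["E4"]],
    F4 = E[["E5"]],
    F5 = E[["E6"]] + E[["E7"]],
    F6 = E[["E8"]],
    F7 = safe_ratio(E[["E2"]], E[["E1"]]),
    F8 = safe_ratio(E[["E3"]], E[["E1"]]),
    F9 = safe_ratio(E[["E4"]], E[["E1"]]),
    F10 = safe_ratio(E[["E5"]], E[["E1"]]),
    F11 = safe_ratio(E[["E6"]] + E[["E7"]], E[["E1"]]),
    F12 = safe_ratio(E[["E8"]], E[["E1"]]),
    F13 = safe_ratio(E[["E4"]] + E[["E5"]], E[["E1"]]),
    F14 = safe_ratio(E[["E5"]], E[["E6"]] + E[["E7"]]),
    F15 = safe_ratio(E[["E4"]] + E[["E5"]],
                     E[["E5"]] + E[["E6"]] + E[["E7"]]),
    F16 = safe_ratio(E[["E4"]], E[["E6"]] + E[["E7"]]),
    F17 = safe_ratio(E[["E3"]], E[["E4"]] + E[["E5"]]),
    F18 = safe_ratio(E[["E4"]], E[["E3"]] + E[["E5"]]),
    F19 = safe_ratio(E[["E5"]], E[["E3"]] + E[["E4"]]),
    F20 = safe_ratio(E[["E2"]], E[["E3"]] + E[["E9"]]),
    F21 = safe_ratio(E[["E5"]], E[["E9"]]),
    F22 = safe_ratio(E[["E6"]] + E[["E7"]], E[["E9"]]),
    F23 = safe_ratio(E[["E5"]], E[["E4"]]),
    F24 = safe_ratio(E[["E2"]] + E[["E3"]], E[["E4"]]),
    F25 = safe_ratio(E[["E2"]] + E[["E6"]], E[["E9"]])
  )
  flagged(vals, E[["E1"]] == 0)
}

# Frequency sets used by the spectral-moment features: the full filtered
# band, the five narrow bands, and beta as a single 13-30 Hz band.
mpf_band_table <- function() {
  tibble(
    set = c("full", "low_delta", "high_delta", "theta", "alpha",
            "beta", "gamma"),
    low = c(0.5, 0.5, 1.2, 4, 8, 13, 30),
    high = c(45, 2, 4, 8, 13, 30, 45)
  )
}

#' Spectral moment features F26-F39
#'
#' Mean power frequency (MPF) and frequency variance (FV), the first and
#' second power-weighted moments of the spectrum restricted to a frequency
#' set S: `MPF_S = sum(f * P(f)) / sum(P(f))` and
#' `FV_S = sum((f - MPF_S)^2 * P(f)) / sum(P(f))` over `f` in S.
#' F26/F33 use the full 0.5-45 Hz range; F27-F32 and F34-F39 use the
#' low-delta, high-delta, theta, alpha, beta (13-30 Hz combined) and gamma
#' bands. Bands with zero power give flagged zeros.
#'
#' @param ps Spectrum from [power_spectrum()].
#' @param scheme Ignored placeholder kept for a uniform module surface; the
#'   moment bands derive from the same edges.
#' @return Named numeric vector `F26`...`F39`.
#' @export
mpf_fv_features <- function(ps, scheme = band_scheme()) {
  bt <- mpf_band_table()
  flag <- FALSE
  moments <- purrr::pmap(bt, function(set, low, high) {
    sel <- ps$freq >= low & ps$freq < high
    p <- ps$power[sel]; f <- ps$freq[sel]
    tot <- sum(p)
    if (tot <= 0) {
      flag <<- TRUE
      c(mpf = 0, fv = 0)
    } else {
      mpf <- sum(f * p) / tot
      c(mpf = mpf, fv = sum((f - mpf)^2 * p) / tot)
    }
  })
  mpf <- vapply(moments, `[[`, numeric(1), "mpf")
  fv <- vapply(moments, `[[`, numeric(1), "fv")
  flagged(stats::setNames(c(mpf, fv), paste0("F", 26:39)), flag)
}

#' All frequency-domain features of one epoch
#'
#' @param epoch Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param nfft Transform length.
#' @param scheme Band table as in [band_scheme()].
#' @return Named numeric vector `F1`...`F39`.
#' @export
freq_features <- function(epoch, fs = 100, nfft = length(epoch),
                          scheme = band_scheme()) {
  ps <- power_spectrum(epoch, nfft = nfft, fs = fs)
  E <- band_powers(ps, scheme)
  c(ratio_features(E), mpf_fv_features(ps, scheme))
}
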