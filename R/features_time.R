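# Time-domain features T1-T15.
#
# All moments are central and divide by N (population convention); the
# standard deviation s = sqrt(T3) is the normalizer shared by the
# difference features and the Hjorth parameters. Degenerate (zero-variance)
# epochs yield 0 for the normalized features, with a "flagged" attribute.

flagged <- function(x, flag) {
  attr(x, "flagged") <- flag
  x
}

#' Basic distributional statistics of one epoch (T1-T9)
#'
#' Peak-to-peak amplitude, mean, population variance and SD, median,
#' skewness, excess kurtosis, maximum and minimum.
#'
#' @param epoch Numeric vector of samples.
#' @return Named numeric vector `T1`...`T9`. For a constant epoch, skewness
#'   and kurtosis are reported as 0 and the result carries
#'   `attr(, "flagged") = TRUE`.
#' @export
basic_stats <- function(epoch) {
  stopifnot(length(epoch) >= 2)
  m <- mean(epoch)
  v <- mean((epoch - m)^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean((epoch - m)^3) / s^3
    kurt <- mean((epoch - m)^4) / s^4 - 3
    flag <- FALSE
  } else {
    skew <- 0; kurt <- 0; flag <- TRUE
  }
  flagged(c(T1 = max(epoch) - min(epoch), T2 = m, T3 = v, T4 = s,
            T5 = median(epoch), T6 = skew, T7 = kurt,
            T8 = max(epoch), T9 = min(epoch)), flag)
}

#' Zero-crossing rate (T10)
#'
#' The epoch is mean-removed first, so crossings are counted against the
#' waveform's own midline. A crossing is a strict sign change between
#' adjacent samples (`x[i] * x[i+1] < 0`; exact zeros do not count), and the
#' count is normalized by `N - 1`.
#'
#' @param epoch Numeric vector of samples.
#' @return Scalar in `[0, 1]`.
#' @export
zero_crossing_rate <- function(epoch) {
  stopifnot(length(epoch) >= 2)
  x <- epoch - mean(epoch)
  sum(x[-length(x)] * x[-1] < 0) / (length(x) - 1)
}

#' Normalized first- and second-difference amplitudes (T11, T12)
#'
#' T11 (AFDN) is the mean absolute first difference `X(n+1) - X(n)` divided
#' by the epoch SD; T12 (ASDN) is the mean absolute lag-2 difference
#' `X(n+2) - X(n)` divided by the epoch SD.
#'
#' @param epoch Numeric vector of samples.
#' @return Named numeric vector `c(T11, T12)`; flagged zeros for a constant
#'   epoch.
#' @export
diff_features <- function(epoch) {
  n <- length(epoch)
  stopifnot(n >= 3)
  s <- pop_sd(epoch)
  if (s == 0) return(flagged(c(T11 = 0, T12 = 0), TRUE))
  d1 <- mean(abs(epoch[-1] - epoch[-n]))
  d2 <- mean(abs(epoch[-(1:2)] - epoch[-((n - 1):n)]))
  flagged(c(T11 = d1 / s, T12 = d2 / s), FALSE)
}

#' Hjorth parameters (T13-T15)
#'
#' Activity is the population variance. Mobility is the ratio of the SD of
#' the first-difference sequence to the signal SD (a mean-frequency proxy).
#' Complexity is the mobility of the first-difference sequence divided by
#' the mobility of the signal (a bandwidth proxy), using the second
#' difference `diff(diff(x))`.
#'
#' @param epoch Numeric vector of samples.
#' @return Named numeric vector `c(T13, T14, T15)`; flagged zeros for a
#'   constant epoch.
#' @export
hjorth <- function(epoch) {
  n <- length(epoch)
  stopifnot(n >= 3)
  s <- pop_sd(epoch)
  if (s == 0) return(flagged(c(T13 = 0, T14 = 0, T15 = 0), TRUE))
  d1 <- diff(epoch)
  d2 <- diff(d1)
  sd1 <- pop_sd(d1)
  sd2 <- pop_sd(d2)
  mob <- sd1 / s
  comp <- if (sd1 > 0) (sd2 / sd1) / mob else 0
  flagged(c(T13 = s^2, T14 = mob, T15 = comp), FALSE)
}

#' All time-domain features of one epoch
#'
#' @param epoch Numeric vector of samples.
#' @return Named numeric vector `T1`...`T15`.
#' @export
time_features <- function(epoch) {
  c(basic_stats(epoch), T10 = zero_crossing_rate(epoch),
    diff_features(epoch), hjorth(epoch))
}
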