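# Nonlinear features: Higuchi fractal dimension (N1), non-stationary index
# (N2), sample entropy (N3). The O(N^2) and O(N * kmax) inner loops live in
# compiled code (src/nonlinear.cpp); these wrappers own the conventions.

#' Higuchi fractal dimension (N1)
#'
#' Curve lengths are computed at lags `k = 1..k_max` (averaged over the `k`
#' possible offsets) and the dimension is the least-squares slope of
#' `ln H(k)` against `-ln k`, evaluated with the closed-form ratio
#' `sum((muH - ln H(k)) (muk + ln k)) / sum((muk + ln k)^2)` where `muk` is
#' minus the mean of `ln k` and `muH` the mean of `ln H(k)`. A straight
#' line gives 1; white noise approaches 2.
#'
#' @param epoch Numeric vector of at least 40 samples.
#' @param k_max Largest lag; default `floor(N / 20)`.
#' @return Scalar dimension estimate; a constant epoch gives a flagged 0.
#' @export
higuchi_fd <- function(epoch, k_max = floor(length(epoch) / 20)) {
  n <- length(epoch)
  stopifnot(n >= 40, k_max >= 2)
  H <- higuchi_lengths(as.numeric(epoch), as.integer(k_max))
  if (any(H <= 0)) return(flagged(0, TRUE))
  lk <- log(seq_len(k_max))
  lH <- log(H)
  mu_k <- -mean(lk)
  mu_H <- mean(lH)
  sum((mu_H - lH) * (mu_k + lk)) / sum((mu_k + lk)^2)
}

#' Non-stationary index (N2)
#'
#' The epoch is split into `m = floor(fraction * N)` contiguous segments of
#' as equal length as possible (the first `N mod m` segments are one sample
#' longer), and the NSI is the population standard deviation of the segment
#' means -- a measure of local-mean drift, in the same units as the signal.
#'
#' @param epoch Numeric vector of at least 20 samples.
#' @param fraction Segment-count fraction of the epoch length.
#' @return Scalar NSI (microvolts for a microvolt signal).
#' @export
nsi <- function(epoch, fraction = 0.15) {
  n <- length(epoch)
  stopifnot(n >= 20)
  m <- floor(fraction * n)
  if (m < 2) stop("too few segments: floor(fraction * N) must be >= 2",
                  call. = FALSE)
  q <- n %/% m
  r <- n %% m
  lens <- c(rep(q + 1L, r), rep(q, m - r))
  grp <- rep.int(seq_len(m), lens)
  means <- as.numeric(tapply(epoch, grp, mean))
  pop_sd(means)
}

#' Sample entropy (N3)
#'
#' `SampEn(m, r, N) = -ln(A / B)` where `B` counts template pairs of length
#' `m` within Chebyshev distance `r = r_coeff * SD(epoch)` and `A` counts
#' the same pairs extended to length `m + 1`. Self-matches are excluded, and
#' both counts run over the `N - m` template starts that admit an
#' `(m + 1)`-length extension. When no template pair matches (`A` or `B`
#' zero) or the epoch is constant, the value is undefined and returned as
#' flagged `NA` rather than regularized.
#'
#' @param epoch Numeric vector of at least `m + 2` samples.
#' @param m Embedding (template) length.
#' @param r_coeff Tolerance as a fraction of the epoch SD.
#' @return Scalar entropy in nats, or flagged `NA` when undefined.
#' @export
sample_entropy <- function(epoch, m = 2, r_coeff = 0.2) {
  n <- length(epoch)
  stopifnot(n >= m + 2)
  s <- pop_sd(epoch)
  if (s == 0) return(flagged(NA_real_, TRUE))
  counts <- sampen_counts(as.numeric(epoch), as.integer(m), r_coeff * s)
  if (counts[1] == 0 || counts[2] == 0) return(flagged(NA_real_, TRUE))
  -log(counts[1] / counts[2])
}

#' All nonlinear features of one epoch
#'
#' @param epoch Numeric vector of samples.
#' @param m,r_coeff Sample-entropy parameters.
#' @param nsi_fraction Segment fraction for the non-stationary index.
#' @return Named numeric vector `c(N1, N2, N3)`; an undefined sample
#'   entropy is reported as 0 so feature tables stay finite.
#' @export
nonlinear_features <- function(epoch, m = 2, r_coeff = 0.2,
                               nsi_fraction = 0.15) {
  se <- sample_entropy(epoch, m = m, r_coeff = r_coeff)
  c(N1 = as.numeric(higuchi_fd(epoch)),
    N2 = nsi(epoch, fraction = nsi_fraction),
    N3 = if (is.na(se)) 0 else as.numeric(se))
}
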