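#' Band-pass filter specification
#'
#' Default preprocessing filter: a linear-phase FIR band-pass over the
#' 0.5-45 Hz EEG band, 401 Hamming-window taps at 100 Hz, applied
#' forward-backward so the output is zero-phase.
#'
#' @param low_hz Lower passband edge in Hz.
#' @param high_hz Upper passband edge in Hz.
#' @param n_taps Odd number of FIR taps.
#' @param window Window tag (currently `"hamming"`).
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 45, n_taps = 401,
                        window = "hamming") {
  stopifnot(low_hz > 0, high_hz > low_hz, n_taps %% 2 == 1, n_taps > 3)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 n_taps = as.integer(n_taps), window = window),
            class = "filter_spec")
}

#' Design a linear-phase FIR band-pass filter
#'
#' Windowed-sinc design via [signal::fir1()]. The returned coefficients are
#' symmetric (linear phase); with the defaults at 100 Hz the response is flat
#' to within a fraction of a dB across 1-40 Hz and attenuates DC and 49 Hz
#' by well over 20 dB.
#'
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Numeric vector of `n_taps` coefficients.
#' @export
design_bandpass <- function(fs = 100, spec = filter_spec()) {
  if (spec$high_hz >= fs / 2) {
    stop("high cutoff must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  win <- switch(spec$window,
    hamming = signal::hamming(spec$n_taps),
    hanning = signal::hanning(spec$n_taps),
    stop("unknown window tag: ", spec$window, call. = FALSE)
  )
  as.numeric(signal::fir1(spec$n_taps - 1,
                          c(spec$low_hz, spec$high_hz) / (fs / 2),
                          type = "pass", window = win))
}

# Centered (zero-phase for symmetric taps) convolution with odd-symmetric
# edge reflection; FFT convolution for long signals, direct otherwise.
fir_zero_phase_pass <- function(x, coeffs) {
  L <- (length(coeffs) - 1) / 2
  n <- length(x)
  left <- 2 * x[1] - x[(L + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - L)]
  xp <- c(left, x, right)
  if (length(xp) > 20000L) {
    m <- length(xp) + length(coeffs) - 1
    nf <- stats::nextn(m, 2)
    y <- Re(fft(fft(c(xp, numeric(nf - length(xp)))) *
                  fft(c(coeffs, numeric(nf - length(coeffs)))),
                inverse = TRUE)) / nf
    y[(2 * L + 1):(2 * L + n)]
  } else {
    y <- stats::filter(xp, coeffs, method = "convolution", sides = 2)
    as.numeric(y[(L + 1):(L + n)])
  }
}

#' Apply a zero-phase FIR filter
#'
#' Filters the signal forward and backward with the (symmetric) FIR
#' coefficients, giving zero phase shift, squared magnitude response, and an
#' output of the same length as the input. Edges are handled by odd
#' reflection padding.
#'
#' @param rec A [raw_recording()] or numeric vector.
#' @param coeffs FIR coefficients from [design_bandpass()].
#' @return Same type as `rec`, filtered.
#' @export
apply_filter <- function(rec, coeffs) {
  x <- if (inherits(rec, "raw_recording")) rec$samples else rec
  if (length(x) <= 3 * length(coeffs)) {
    stop("signal too short to filter: need more than 3 * n_taps samples",
         call. = FALSE)
  }
  y <- fir_zero_phase_pass(fir_zero_phase_pass(x, coeffs), coeffs)
  if (inherits(rec, "raw_recording")) {
    raw_recording(y, rec$fs, rec$channel)
  } else {
    y
  }
}
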