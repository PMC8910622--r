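# Seeded stage-conditioned synthetic EEG: each stage is a weighted sum of
# band-limited Gaussian noise components (band-passed with the same FIR
# designs as the preprocessing module, applied in the DFT domain), plus
# stage-specific transient events (sleep spindles and K-complexes in N2),
# scaled to a stage-dependent amplitude.

#' Default per-stage epoch counts
#'
#' The balanced corpus layout used as the generator default: 2029 epochs
#' for each of W, N1 and N2, 1671 for N3 and 1938 for REM (9696 in total).
#'
#' @return Named integer vector.
#' @export
default_stage_counts <- function() {
  c(W = 2029L, N1 = 2029L, N2 = 2029L, N3 = 1671L, REM = 1938L)
}

#' Synthetic EEG recipe
#'
#' Per-stage relative band gains over the seven rhythm bands of
#' [band_scheme()], per-stage amplitude scales (relative to `base_uv`),
#' a broadband noise floor, and N2 event parameters (12-14 Hz spindle
#' bursts and biphasic K-complex transients). The default recipe mimics
#' textbook stage physiology: alpha-dominant W, theta-dominant N1,
#' spindle-bearing N2, high-amplitude delta N3, and low-voltage mixed REM
#' with a beta/gamma admixture that keeps REM separable from N1. With
#' `hard = TRUE` the REM gains are pulled toward N1 to mimic the real
#' REM/N1 confusability, for qualitative demonstrations.
#'
#' @param hard Narrow the REM/N1 gap.
#' @param base_uv Base amplitude scale in microvolts.
#' @param noise_floor Broadband white-noise gain.
#' @return List of class `synthetic_recipe`.
#' @export
synthetic_recipe <- function(hard = FALSE, base_uv = 10, noise_floor = 0.1) {
  gains <- rbind(
    W   = c(0.25, 0.25, 0.30, 1.00, 0.50, 0.35, 0.15),
    N1  = c(0.35, 0.40, 1.00, 0.30, 0.20, 0.10, 0.05),
    N2  = c(0.70, 0.80, 0.80, 0.20, 0.15, 0.10, 0.05),
    N3  = c(2.00, 1.60, 0.40, 0.10, 0.05, 0.05, 0.02),
    REM = c(0.30, 0.35, 0.70, 0.15, 0.60, 0.50, 0.25)
  )
  colnames(gains) <- band_scheme()$band
  if (hard) {
    gains["REM", ] <- 0.6 * gains["REM", ] + 0.4 * gains["N1", ]
  }
  structure(
    list(
      gains = gains,
      amplitude = c(W = 1.0, N1 = 0.9, N2 = 1.3, N3 = 2.5, REM = 0.8),
      base_uv = base_uv,
      noise_floor = noise_floor,
      spindle_rate = 2, spindle_freq = c(12, 14), spindle_amp = 2,
      kcomplex_rate = 1, kcomplex_amp = 4
    ),
    class = "synthetic_recipe"
  )
}

# DFT-domain transfer functions of the per-band FIR designs, computed once
# per (fs, n) and reused across epochs.
band_responses <- function(fs, n, n_taps = 401) {
  sch <- band_scheme()
  H <- vapply(seq_len(nrow(sch)), function(i) {
    co <- design_bandpass(fs, filter_spec(sch$low[i], sch$high[i],
                                          n_taps = n_taps))
    fft(c(co, numeric(n - length(co))))
  }, complex(n))
  colnames(H) <- sch$band
  H
}

#' Generate one synthetic epoch
#'
#' @param stage Stage label.
#' @param recipe A [synthetic_recipe()].
#' @param seed Integer seed; the same `(stage, seed)` pair always yields
#'   identical samples.
#' @param fs Sampling rate in Hz.
#' @param n Samples per epoch.
#' @param responses Optional precomputed [band_responses()] matrix (used
#'   internally to amortize the filter designs over a dataset).
#' @return Numeric vector of `n` samples (microvolts).
#' @export
generate_epoch <- function(stage, recipe = synthetic_recipe(), seed = 1,
                           fs = 100, n = 3000, responses = NULL) {
  stage <- match.arg(as.character(stage), sleep_stages())
  if (is.null(responses)) responses <- band_responses(fs, n)
  g <- recipe$gains[stage, ]
  t <- (seq_len(n) - 1) / fs
  withr::with_seed(seed, {
    sig <- numeric(n)
    for (b in seq_along(g)) {
      w <- rnorm(n)
      sig <- sig + g[b] * Re(fft(fft(w) * responses[, b],
                                 inverse = TRUE)) / n
    }
    sig <- sig + recipe$noise_floor * rnorm(n)
    if (stage == "N2") {
      for (k in seq_len(rpois(1, recipe$spindle_rate))) {
        ctr <- runif(1, 1, max(t) - 1)
        f <- runif(1, recipe$spindle_freq[1], recipe$spindle_freq[2])
        phase <- runif(1, 0, 2 * pi)
        sig <- sig + recipe$spindle_amp *
          sin(2 * pi * f * t + phase) * exp(-(t - ctr)^2 / (2 * 0.5^2))
      }
      for (k in seq_len(rpois(1, recipe$kcomplex_rate))) {
        ctr <- runif(1, 1, max(t) - 1)
        tau <- 0.2
        sig <- sig - recipe$kcomplex_amp * ((t - ctr) / tau) *
          exp(-(t - ctr)^2 / (2 * tau^2))
      }
    }
  })
  recipe$base_uv * recipe$amplitude[[stage]] * sig
}

#' Generate a labelled synthetic dataset
#'
#' Generates `counts[stage]` epochs per stage, each from an independent
#' per-epoch seed derived deterministically from the master seed.
#'
#' @param counts Named per-stage epoch counts; default
#'   [default_stage_counts()].
#' @param recipe A [synthetic_recipe()].
#' @param seed Master integer seed.
#' @param fs Sampling rate in Hz.
#' @param n Samples per epoch.
#' @return An [epoched_recording()].
#' @export
generate_dataset <- function(counts = default_stage_counts(),
                             recipe = synthetic_recipe(), seed = 1,
                             fs = 100, n = 3000) {
  counts <- counts[names(counts) %in% sleep_stages()]
  labels <- rep(names(counts), times = counts)
  if (length(labels) == 0) {
    return(epoched_recording(matrix(numeric(0), 0, n), fs, character(0)))
  }
  responses <- band_responses(fs, n)
  ep <- t(vapply(seq_along(labels), function(i) {
    generate_epoch(labels[i], recipe, seed = derive_seed(seed, i),
                   fs = fs, n = n, responses = responses)
  }, numeric(n)))
  epoched_recording(ep, fs, labels)
}
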