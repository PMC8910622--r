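#' Names of the 57 features
#'
#' @return Character vector: `T1`-`T15`, `F1`-`F39`, `N1`-`N3`.
#' @export
feature_names <- function() {
  c(paste0("T", 1:15), paste0("F", 1:39), paste0("N", 1:3))
}

#' Extract all 57 features from one epoch
#'
#' @param epoch Numeric vector (one 30-s epoch, 3000 samples at 100 Hz by
#'   convention).
#' @param fs Sampling rate in Hz.
#' @param nfft Transform length for the periodogram.
#' @param scheme Rhythm-band table, see [band_scheme()].
#' @param m,r_coeff Sample-entropy parameters.
#' @param nsi_fraction Segment fraction for the non-stationary index.
#' @return Named numeric vector of length 57.
#' @export
epoch_features <- function(epoch, fs = 100, nfft = length(epoch),
                           scheme = band_scheme(), m = 2, r_coeff = 0.2,
                           nsi_fraction = 0.15) {
  out <- c(time_features(epoch),
           freq_features(epoch, fs = fs, nfft = nfft, scheme = scheme),
           nonlinear_features(epoch, m = m, r_coeff = r_coeff,
                              nsi_fraction = nsi_fraction))
  names(out) <- feature_names()
  out
}

#' Extract the feature table of an epoched recording
#'
#' Computes the full 57-dimensional feature vector for every epoch and
#' returns a tidy table with the stage label in the first column -- the
#' package's interchange format between recording, screening and modelling
#' steps.
#'
#' @param er An [epoched_recording()] (or a numeric matrix of epochs, with
#'   `labels` supplied).
#' @param labels Stage labels when `er` is a bare matrix.
#' @param fs Sampling rate in Hz (taken from `er` when available).
#' @inheritParams epoch_features
#' @return Tibble with columns `stage` (factor) and `T1`...`N3`.
#' @export
extract_features <- function(er, labels = NULL, fs = NULL,
                             nfft = NULL, scheme = band_scheme(),
                             m = 2, r_coeff = 0.2, nsi_fraction = 0.15) {
  if (inherits(er, "epoched_recording")) {
    mat <- er$epochs
    labels <- er$labels
    fs <- fs %||% er$fs
  } else {
    mat <- as.matrix(er)
    if (is.null(labels)) stop("labels required for a bare epoch matrix",
                              call. = FALSE)
    fs <- fs %||% 100
  }
  nfft <- nfft %||% ncol(mat)
  feats <- t(vapply(
    seq_len(nrow(mat)),
    function(i) epoch_features(mat[i, ], fs = fs, nfft = nfft,
                               scheme = scheme, m = m, r_coeff = r_coeff,
                               nsi_fraction = nsi_fraction),
    numeric(57)
  ))
  dplyr::bind_cols(tibble(stage = stage_factor(labels)), as_tibble(feats))
}
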