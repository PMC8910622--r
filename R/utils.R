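#' The five AASM sleep stages
#'
#' Stage labels used throughout the package, in conventional depth order:
#' wake, the three non-REM depths, and REM.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
#' @examples
#' sleep_stages()
sleep_stages <- function() c("W", "N1", "N2", "N3", "REM")

#' Coerce to a sleep-stage factor
#'
#' @param x Character or factor vector of stage labels.
#' @return Factor with levels [sleep_stages()].
#' @export
stage_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), sleep_stages())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = sleep_stages())
}

# Population (divide-by-N) variance and SD: the moment conventions used by
# every feature in the package.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Deterministic per-item seed derived from a master seed, kept inside the
# 32-bit integer range R accepts.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * as.numeric(i)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
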