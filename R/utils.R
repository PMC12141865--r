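# Internal helpers: classed conditions, rounding, deterministic sub-seeding.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = c("phagekit_validation_error", "phagekit_error"), ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = c("phagekit_format_error", "phagekit_error"), ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = c("phagekit_data_error", "phagekit_error"), ...)
}

abort_range <- function(msg, ...) {
  rlang::abort(msg, class = c("phagekit_range_error", "phagekit_error"), ...)
}

abort_degenerate_control <- function(msg, ...) {
  rlang::abort(msg, class = c("phagekit_degenerate_control_error", "phagekit_error"), ...)
}

abort_generation <- function(msg, ...) {
  rlang::abort(msg, class = c("phagekit_generation_error", "phagekit_error"), ...)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all percentages printed as
#' integers. `round()` in R rounds half to even, which would turn 44.5 into
#' 44; laboratory reports round it to 45.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(44.5, 45.5, 44.68))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 31-bit sub-seed from a global seed and a string key.
# Stable across sessions (no dependence on R's RNG state), so adding wells
# to a simulated plate never perturbs existing wells.
substream_seed <- function(seed, key) {
  m <- 2147483647 # 2^31 - 1, keeps exact integer arithmetic in doubles
  h <- 0
  for (c in utf8ToInt(paste0(key))) {
    h <- (h * 31 + c) %% m
  }
  as.integer((h + (seed %% m) * 48271) %% m)
}

# Shared trapezoid on aligned vectors (no interpolation).
trapz_vec <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

`%||%` <- rlang::`%||%`
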