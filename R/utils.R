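#' @keywords internal
"_PACKAGE"

# Validation helpers. All user-facing validation errors name the offending
# field so callers can trace a bad configuration back to its source.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok)
    abort_field(field, sprintf("must lie in [%g, %g]", lower, upper))
  invisible(x)
}

#' Noise specification for the synthetic-data generators
#'
#' Couples a Gaussian peak-height noise level (expressed as a fraction of a
#' reference intensity) with an integer seed so that every generated dataset
#' is bit-for-bit reproducible.
#'
#' @param intensity_sd Noise standard deviation as a fraction of the
#'   reference peak height (dimensionless, `>= 0`).
#' @param seed Integer seed controlling the random stream.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(0.01, seed = 7)
#' @export
noise_spec <- function(intensity_sd = 0, seed = 1L) {
  check_number(intensity_sd, "intensity_sd", lower = 0)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_field("seed", "must be a single integer")
  structure(list(intensity_sd = intensity_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# Run `expr` under the spec's seed without disturbing the caller's RNG state.
with_noise_seed <- function(noise, expr) {
  withr::with_seed(noise$seed, expr)
}
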