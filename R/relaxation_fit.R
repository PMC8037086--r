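# Estimation of R1/R2 relaxation rates and heteronuclear NOEs from
# peak-intensity data: two-parameter single-exponential fits with
# Monte-Carlo errors, and saturated/unsaturated height ratios with
# duplicate-based error propagation.

#' Fit a single-exponential decay to a relaxation series
#'
#' Least-squares fit of \eqn{I(t) = I_0 e^{-R t}} by Levenberg-Marquardt,
#' started from the log-linear estimate (slope of `ln I` vs `t` over the
#' positive intensities). No baseline offset is fitted: the decay model is a
#' pure two-parameter exponential.
#'
#' Failures (non-convergence, non-positive rate at the optimum, degenerate
#' constant intensities) are returned as flagged records rather than
#' errors, so a few bad residues do not abort a data set; series with fewer
#' than 4 points are a validation error.
#'
#' @param series A [relaxation_series()].
#' @return A `rate_estimate`: list with `residue_id`, `rate`, `rate_error`
#'   (0 until [mc_error()] is run), `I0`, `fit_rss`, `ok`, `reason`.
#' @examples
#' s <- simulate_decay_series(2, 100, default_delays("T1"))
#' fit_exponential(s)
#' @export
fit_exponential <- function(series) {
  stopifnot(inherits(series, "relaxation_series"))
  t <- series$delays; I <- series$intensities
  if (length(t) < 4L)
    abort_field("delays", "at least 4 points are required for fitting")
  failed <- function(reason) {
    structure(list(residue_id = series$residue_id, rate = NA_real_,
                   rate_error = NA_real_, I0 = NA_real_, fit_rss = NA_real_,
                   ok = FALSE, reason = reason),
              class = "rate_estimate")
  }
  if (diff(range(I)) == 0) return(failed("constant intensities"))
  pos <- I > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(I[pos]) ~ t[pos])
    start <- list(I0 = exp(unname(stats::coef(lf)[1])),
                  rate = -unname(stats::coef(lf)[2]))
  } else {
    start <- list(I0 = max(abs(I)), rate = 1 / max(t[t > 0], 1))
  }
  if (!is.finite(start$rate) || start$rate <= 0) start$rate <- 1 / stats::median(t[t > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 * exp(-rate * t), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("no convergence"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["rate"]]) || cf[["rate"]] <= 0)
    return(failed("non-positive rate at optimum"))
  structure(list(residue_id = series$residue_id,
                 rate = unname(cf[["rate"]]), rate_error = 0,
                 I0 = unname(cf[["I0"]]),
                 fit_rss = sum(stats::resid(fit)^2),
                 ok = TRUE, reason = NA_character_),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<rate_estimate> residue %d: rate %.4f +/- %.4f s^-1 (I0 %.4g)\n",
                x$residue_id, x$rate, x$rate_error, x$I0))
  else
    cat(sprintf("<rate_estimate> residue %d: FAILED (%s)\n",
                x$residue_id, x$reason))
  invisible(x)
}

#' Monte-Carlo error for a fitted relaxation rate
#'
#' Generates `n_mc` synthetic copies of the best-fit decay with Gaussian
#' noise of sd `noise_sd`, refits each, and reports the standard deviation
#' of the refitted rates as `rate_error`.
#'
#' @param series The fitted [relaxation_series()] (supplies the delay grid).
#' @param fit A successful `rate_estimate` from [fit_exponential()].
#' @param n_mc Number of Monte-Carlo replicates (default 500, >= 100).
#' @param noise_sd Intensity noise sd (> 0), typically from
#'   [estimate_noise_from_duplicates()].
#' @param seed Integer seed (results are deterministic given the seed).
#' @return The `rate_estimate` with `rate_error` filled in.
#' @export
mc_error <- function(series, fit, n_mc = 500L, noise_sd, seed = 1L) {
  stopifnot(inherits(fit, "rate_estimate"))
  if (!isTRUE(fit$ok)) abort_field("fit", "cannot attach errors to a failed fit")
  if (n_mc < 100L) abort_field("n_mc", "must be >= 100")
  check_number(noise_sd, "noise_sd", lower = 0, allow_equal = FALSE)
  t <- series$delays
  ideal <- fit$I0 * exp(-fit$rate * t)
  rates <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_mc), function(i) {
      I <- ideal + stats::rnorm(length(t), 0, noise_sd)
      f <- tryCatch(
        minpack.lm::nlsLM(I ~ I0 * exp(-rate * t),
                          start = list(I0 = fit$I0, rate = fit$rate)),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else unname(stats::coef(f)[["rate"]])
    }, numeric(1))
  })
  fit$rate_error <- stats::sd(rates, na.rm = TRUE)
  fit
}

#' Estimate intensity noise from duplicate spectra
#'
#' For duplicate measurements of the same quantities, the per-measurement
#' noise sd is `sd(a - b) / sqrt(2)` (differences carry the noise of both
#' copies). Accepts either two [relaxation_series()] recorded on the same
#' delay grid or two plain numeric vectors of matched peak heights.
#'
#' @param series_a,series_b The duplicate pair.
#' @return Estimated intensity standard deviation.
#' @examples
#' a <- simulate_decay_series(2, 100, noise = noise_spec(0.01, 1))
#' b <- simulate_decay_series(2, 100, noise = noise_spec(0.01, 2))
#' estimate_noise_from_duplicates(a, b)
#' @export
estimate_noise_from_duplicates <- function(series_a, series_b) {
  if (inherits(series_a, "relaxation_series")) {
    if (!isTRUE(all.equal(series_a$delays, series_b$delays)))
      abort_field("series_b", "delay grids must match the first series")
    d <- series_a$intensities - series_b$intensities
  } else {
    if (length(series_a) != length(series_b))
      abort_field("series_b", "length must match the first vector")
    d <- series_a - series_b
  }
  if (length(d) < 2L) return(abs(d) / sqrt(2))
  stats::sd(d) / sqrt(2)
}

#' Heteronuclear NOE from saturated/unsaturated peak heights
#'
#' `NOE = I_sat / I_unsat` per residue, with first-order error propagation
#' from duplicate-derived height noise:
#' \eqn{\sigma_{NOE} = |NOE| \sqrt{(\sigma_{sat}/I_{sat})^2 +
#' (\sigma_{unsat}/I_{unsat})^2}}. If a duplicate pair is supplied, heights
#' are averaged across duplicates and the height sds are estimated from the
#' duplicate differences; otherwise `noe_error` is `NA`.
#'
#' @param residue_id Integer residue numbers.
#' @param sat_heights,unsat_heights Peak heights with/without saturation.
#' @param sat_dup,unsat_dup Optional duplicate heights (same residues).
#' @return Data frame of class `xnoe_estimate` with columns `residue_id`,
#'   `noe`, `noe_error`, `ok`.
#' @examples
#' compute_xnoe(1, 80, 100)
#' @export
compute_xnoe <- function(residue_id, sat_heights, unsat_heights,
                         sat_dup = NULL, unsat_dup = NULL) {
  n <- length(residue_id)
  stopifnot(length(sat_heights) == n, length(unsat_heights) == n)
  have_dup <- !is.null(sat_dup) && !is.null(unsat_dup)
  if (have_dup) {
    stopifnot(length(sat_dup) == n, length(unsat_dup) == n)
    sd_sat <- estimate_noise_from_duplicates(sat_heights, sat_dup)
    sd_unsat <- estimate_noise_from_duplicates(unsat_heights, unsat_dup)
    sat <- (sat_heights + sat_dup) / 2
    unsat <- (unsat_heights + unsat_dup) / 2
    # averaging two duplicates halves the variance
    sd_sat <- sd_sat / sqrt(2); sd_unsat <- sd_unsat / sqrt(2)
  } else {
    sat <- sat_heights; unsat <- unsat_heights
    sd_sat <- NA_real_; sd_unsat <- NA_real_
  }
  ok <- unsat > 0
  noe <- ifelse(ok, sat / unsat, NA_real_)
  err <- if (have_dup)
    abs(noe) * sqrt((sd_sat / sat)^2 + (sd_unsat / unsat)^2)
  else rep(NA_real_, n)
  out <- data.frame(residue_id = as.integer(residue_id), noe = noe,
                    noe_error = ifelse(ok, err, NA_real_), ok = ok)
  class(out) <- c("xnoe_estimate", "data.frame")
  out
}

#' Fit a table of relaxation series
#'
#' Convenience driver: fits every (residue, replicate) series in a long
#' table, optionally attaching Monte-Carlo errors.
#'
#' @param tbl Data frame with columns `residue`, `delay_s`, `intensity`,
#'   `replicate` (as written by [write_delay_csv()]).
#' @param n_mc Monte-Carlo replicates for errors; `0` skips error estimation.
#' @param noise_sd Intensity noise sd for the Monte-Carlo step.
#' @param seed Integer seed.
#' @return Data frame with one row per residue/replicate: `residue`,
#'   `replicate`, `rate`, `rate_error`, `I0`, `ok`.
#' @export
fit_rate_table <- function(tbl, n_mc = 0L, noise_sd = NULL, seed = 1L) {
  stopifnot(all(c("residue", "delay_s", "intensity", "replicate") %in%
                names(tbl)))
  keys <- unique(tbl[, c("residue", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tbl[tbl$residue == keys$residue[i] &
               tbl$replicate == keys$replicate[i], ]
    s <- relaxation_series(keys$residue[i], sub$delay_s, sub$intensity,
                           keys$replicate[i])
    f <- fit_exponential(s)
    if (isTRUE(f$ok) && n_mc > 0L)
      f <- mc_error(s, f, n_mc = n_mc, noise_sd = noise_sd,
                    seed = seed + keys$residue[i])
    data.frame(residue = f$residue_id, replicate = keys$replicate[i],
               rate = f$rate, rate_error = f$rate_error, I0 = f$I0,
               ok = f$ok)
  })
  do.call(rbind, rows)
}
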