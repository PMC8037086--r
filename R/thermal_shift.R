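# Boltzmann-sigmoid fitting of thermal-shift (differential scanning
# fluorimetry) melt curves: window truncation, per-replicate fits,
# replicate aggregation and delta-Tm between constructs.

#' Truncate a melt curve to its transition window
#'
#' SYPRO-orange curves decay after the unfolding transition as the dye
#' partitions out of aggregates; the sigmoid is therefore fitted only from
#' the pre-transition fluorescence minimum through the global maximum.
#' The window is recorded on the returned curve.
#'
#' @param curve A [melt_curve()] with at least 10 points.
#' @return The truncated `melt_curve` with attribute `fit_window`
#'   (degC range), or a flagged failure (`list(ok = FALSE, reason = ...)`)
#'   when no rising transition exists.
#' @export
truncate_transition <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  if (length(curve$temperatures) < 10L)
    abort_field("curve", "at least 10 points are required")
  f <- curve$fluorescence
  i_max <- which.max(f)
  if (i_max == 1L)
    return(list(ok = FALSE, reason = "no rising transition"))
  i_min <- which.min(f[seq_len(i_max)])
  if (f[i_max] - f[i_min] <= 0 ||
      !isTRUE(f[i_max] - f[i_min] > 1e-12 * max(abs(f), 1)))
    return(list(ok = FALSE, reason = "flat curve"))
  keep <- seq(i_min, i_max)
  out <- melt_curve(curve$temperatures[keep], f[keep],
                    curve$replicate_id, curve$construct_label)
  attr(out, "fit_window") <- range(curve$temperatures[keep])
  out
}

#' Fit the Boltzmann sigmoid to a melt curve
#'
#' Least-squares fit of
#' \deqn{F(T) = LL + \frac{UL - LL}{1 + \exp((T_m - T)/a)}}
#' by Levenberg-Marquardt. The initial `Tm` is the temperature of the
#' maximum first difference of the fluorescence; baselines start at the
#' observed extremes. The fitted `Tm` is, analytically, the inflection
#' temperature of the sigmoid.
#'
#' @param curve A [melt_curve()], normally already passed through
#'   [truncate_transition()] (done internally when `truncate = TRUE`).
#' @param truncate Apply [truncate_transition()] first (default `TRUE`).
#' @return A `boltzmann_fit`: list with `Tm`, `slope`, `baseline_low`,
#'   `baseline_high`, `Tm_error` (NA until replicates are aggregated),
#'   `fit_window`, `construct_label`, `ok`, `reason`.
#' @examples
#' fit_boltzmann(simulate_melt_curve(60, 1.5))
#' @export
fit_boltzmann <- function(curve, truncate = TRUE) {
  stopifnot(inherits(curve, "melt_curve"))
  label <- curve$construct_label
  failed <- function(reason) {
    list(Tm = NA_real_, slope = NA_real_, baseline_low = NA_real_,
         baseline_high = NA_real_, Tm_error = NA_real_,
         fit_window = c(NA_real_, NA_real_), construct_label = label,
         ok = FALSE, reason = reason)
  }
  if (truncate) {
    curve <- truncate_transition(curve)
    if (!is.null(curve$ok) && !isTRUE(curve$ok))
      return(structure(failed(curve$reason), class = "boltzmann_fit"))
  }
  temp <- curve$temperatures; f <- curve$fluorescence
  window <- attr(curve, "fit_window")
  if (is.null(window)) window <- range(temp)
  d1 <- diff(f)
  start <- list(LL = min(f), UL = max(f),
                Tm = temp[which.max(d1)], a = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ LL + (UL - LL) / (1 + exp((Tm - temp) / a)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(structure(failed("no convergence"),
                                     class = "boltzmann_fit"))
  cf <- as.list(stats::coef(fit))
  if (!is.finite(cf$Tm) || cf$a <= 0)
    return(structure(failed("degenerate optimum"), class = "boltzmann_fit"))
  structure(list(Tm = cf$Tm, slope = cf$a, baseline_low = cf$LL,
                 baseline_high = cf$UL, Tm_error = NA_real_,
                 fit_window = window, construct_label = label,
                 ok = TRUE, reason = NA_character_),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<boltzmann_fit> %s: Tm %.2f degC (slope %.2f, window %.1f-%.1f)\n",
                x$construct_label, x$Tm, x$slope,
                x$fit_window[1], x$fit_window[2]))
  else
    cat(sprintf("<boltzmann_fit> %s: FAILED (%s)\n", x$construct_label,
                x$reason))
  invisible(x)
}

#' Aggregate replicate Boltzmann fits
#'
#' Replicate-level Tm values are combined as their mean with the sample
#' standard deviation as `Tm_error` (the convention behind the reported
#' `Tm +/- err`); the standard error of the mean is available via
#' `error = "sem"`.
#'
#' @param fits List of successful `boltzmann_fit` objects for one construct.
#' @param error `"sd"` (default) or `"sem"`.
#' @return A `boltzmann_fit` carrying the aggregated `Tm` and `Tm_error`;
#'   a single replicate passes through with `Tm_error = NA`.
#' @export
aggregate_replicates <- function(fits, error = c("sd", "sem")) {
  error <- match.arg(error)
  fits <- Filter(function(f) isTRUE(f$ok), fits)
  if (length(fits) == 0L) abort_field("fits", "no successful fits")
  tms <- vapply(fits, `[[`, numeric(1), "Tm")
  out <- fits[[1]]
  out$Tm <- mean(tms)
  out$slope <- mean(vapply(fits, `[[`, numeric(1), "slope"))
  out$n_replicates <- length(fits)
  if (length(fits) == 1L) {
    out$Tm_error <- NA_real_
  } else {
    s <- stats::sd(tms)
    out$Tm_error <- if (error == "sd") s else s / sqrt(length(tms))
  }
  out
}

#' Thermal shift between two constructs
#'
#' `delta_Tm = Tm(a) - Tm(b)` with the replicate errors combined in
#' quadrature.
#'
#' @param fit_a,fit_b Aggregated `boltzmann_fit` objects.
#' @return List with `delta_Tm`, `error`, and the two construct labels.
#' @export
delta_tm <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "boltzmann_fit"), inherits(fit_b, "boltzmann_fit"))
  err <- sqrt(sum(c(fit_a$Tm_error, fit_b$Tm_error)^2, na.rm = TRUE))
  list(delta_Tm = fit_a$Tm - fit_b$Tm, error = err,
       constructs = c(fit_a$construct_label, fit_b$construct_label))
}

#' Fit every replicate melt curve in a long table
#'
#' @param tbl Data frame with columns `temperature_C`, `fluorescence`,
#'   `replicate`, `construct` (as written by [write_melt_csv()]).
#' @param error Aggregation error convention, see [aggregate_replicates()].
#' @return Named list of aggregated `boltzmann_fit` objects, one per
#'   construct.
#' @export
fit_melt_table <- function(tbl, error = "sd") {
  stopifnot(all(c("temperature_C", "fluorescence", "replicate",
                  "construct") %in% names(tbl)))
  out <- list()
  for (cons in unique(tbl$construct)) {
    sub <- tbl[tbl$construct == cons, ]
    fits <- lapply(unique(sub$replicate), function(r) {
      s <- sub[sub$replicate == r, ]
      s <- s[order(s$temperature_C), ]
      fit_boltzmann(melt_curve(s$temperature_C, s$fluorescence, r, cons))
    })
    out[[cons]] <- aggregate_replicates(fits, error = error)
  }
  out
}
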