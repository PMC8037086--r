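# Synthetic-data generators. Raw spectra, peak heights and per-residue
# relaxation rates for Aha1 are not publicly deposited, so every downstream
# stage is exercised against data generated here from known ground truth;
# the truth is always returned alongside the data so recovery tests are
# self-checking.

#' Default relaxation delay grids
#'
#' The delay series used for the T1 and T2 experiments on the two-domain
#' construct: T1 10, 20, 60, 100, 160, 320, 640, 1280, 1800, 2560 ms;
#' T2 10, 30, 50, 70, 90, 110, 130, 150 ms. The single-domain experiments
#' used T1 10, 40, 80, 160, 320, 640, 1280, 2560 ms and T2 10, 30, 70, 90,
#' 110, 150, 190, 210 ms (`variant = "domain"`).
#'
#' @param experiment `"T1"` or `"T2"`.
#' @param variant `"full"` (two-domain construct) or `"domain"`.
#' @return Numeric vector of delays in seconds.
#' @examples
#' default_delays("T1")
#' @export
default_delays <- function(experiment = c("T1", "T2"),
                           variant = c("full", "domain")) {
  experiment <- match.arg(experiment)
  variant <- match.arg(variant)
  ms <- switch(variant,
    full = switch(experiment,
      T1 = c(10, 20, 60, 100, 160, 320, 640, 1280, 1800, 2560),
      T2 = c(10, 30, 50, 70, 90, 110, 130, 150)),
    domain = switch(experiment,
      T1 = c(10, 40, 80, 160, 320, 640, 1280, 2560),
      T2 = c(10, 30, 70, 90, 110, 150, 190, 210)))
  ms / 1000
}

#' Simulate a single-exponential relaxation decay series
#'
#' Generates peak intensities `I0 * exp(-rate * t)` on the given delay grid
#' with additive Gaussian noise of standard deviation
#' `noise$intensity_sd * I0`.
#'
#' @param rate Decay rate, s^-1.
#' @param I0 Intensity at zero delay (arbitrary units).
#' @param delays Relaxation delays in seconds (non-negative, non-empty).
#' @param noise A [noise_spec()].
#' @param residue_id,replicate_id Identifiers carried into the series.
#' @return A `relaxation_series` object (see [relaxation_series()]).
#' @examples
#' simulate_decay_series(2, 100, default_delays("T2"), noise_spec(0.01, 1))
#' @export
simulate_decay_series <- function(rate, I0, delays = default_delays("T1"),
                                  noise = noise_spec(),
                                  residue_id = 1L, replicate_id = 1L) {
  check_number(rate, "rate")
  check_number(I0, "I0")
  if (length(delays) == 0L || any(delays < 0))
    abort_field("delays", "must be non-empty and non-negative")
  ideal <- I0 * exp(-rate * delays)
  noisy <- with_noise_seed(noise,
    ideal + stats::rnorm(length(delays), 0, noise$intensity_sd * I0))
  relaxation_series(residue_id, delays, noisy, replicate_id)
}

#' Simulate a saturated/unsaturated heteronuclear NOE measurement
#'
#' The steady-state XNOE is measured as the ratio of peak heights with and
#' without proton saturation; this generates the paired heights, optionally
#' in duplicate (duplicates share the truth and differ only in noise).
#'
#' @param noe_true True NOE ratio.
#' @param I_ref Reference (unsaturated) peak height.
#' @param noise A [noise_spec()]; Gaussian sd is `intensity_sd * I_ref`.
#' @param n_duplicates Number of duplicate measurements (>= 1).
#' @return Data frame with columns `duplicate`, `sat`, `unsat`.
#' @examples
#' simulate_xnoe_measurement(0.78, 1e6, noise_spec(0.02, 3), n_duplicates = 2)
#' @export
simulate_xnoe_measurement <- function(noe_true, I_ref,
                                      noise = noise_spec(),
                                      n_duplicates = 1L) {
  check_number(noe_true, "noe_true")
  check_number(I_ref, "I_ref")
  if (n_duplicates < 1L) abort_field("n_duplicates", "must be >= 1")
  sd <- noise$intensity_sd * I_ref
  with_noise_seed(noise, {
    data.frame(
      duplicate = seq_len(n_duplicates),
      sat = noe_true * I_ref + stats::rnorm(n_duplicates, 0, sd),
      unsat = I_ref + stats::rnorm(n_duplicates, 0, sd))
  })
}

#' Simulate a thermal-shift melt curve
#'
#' Boltzmann sigmoid
#' \deqn{F(T) = LL + \frac{UL - LL}{1 + \exp((T_m - T)/a)}}
#' sampled on a temperature grid with additive Gaussian noise whose sd is
#' `noise$intensity_sd * (UL - LL)`. The default grid covers the 25-99
#' degC ramp of the assay at 0.5 degC spacing.
#'
#' @param Tm Melting temperature, degC. A `Tm` outside the grid triggers a
#'   warning (the fit may still be attempted) but not an error.
#' @param slope Transition width parameter `a`, degC (> 0).
#' @param baselines Length-2 numeric `(low, high)` fluorescence baselines.
#' @param T_grid Temperature grid, degC.
#' @param noise A [noise_spec()].
#' @param replicate_id,construct_label Identifiers carried into the curve.
#' @return A `melt_curve` object (see [melt_curve()]).
#' @examples
#' simulate_melt_curve(72.41, 1.5, noise = noise_spec(0.01, 1))
#' @export
simulate_melt_curve <- function(Tm, slope, baselines = c(0, 1),
                                T_grid = seq(25, 99, by = 0.5),
                                noise = noise_spec(),
                                replicate_id = 1L,
                                construct_label = "construct") {
  check_number(Tm, "Tm")
  check_number(slope, "slope", lower = 0, allow_equal = FALSE)
  if (length(baselines) != 2L) abort_field("baselines", "must be (low, high)")
  if (Tm < min(T_grid) || Tm > max(T_grid))
    warning("Tm lies outside the temperature grid; fit may be unreliable")
  f <- baselines[1] + (baselines[2] - baselines[1]) /
    (1 + exp((Tm - T_grid) / slope))
  amp <- abs(baselines[2] - baselines[1])
  noisy <- with_noise_seed(noise,
    f + stats::rnorm(length(T_grid), 0, noise$intensity_sd * amp))
  melt_curve(T_grid, noisy, replicate_id, construct_label)
}

#' Synthetic assigned HSQC peak list
#'
#' Random but reproducible peak list with chemistry-plausible amide shifts
#' (1H 6.5-10.5 ppm, 15N 103-131 ppm) and log-normal heights, used as the
#' base list for titration simulations.
#'
#' @param residues Integer residue numbers.
#' @param seed Integer seed.
#' @param mean_height Geometric mean peak height.
#' @return A `peak_list` object.
#' @examples
#' synthetic_hsqc_peaklist(1:20, seed = 1)
#' @export
synthetic_hsqc_peaklist <- function(residues, seed = 1L, mean_height = 1e6) {
  withr::with_seed(as.integer(seed), {
    peak_list(
      residue = as.integer(residues),
      w_H = stats::runif(length(residues), 6.5, 10.5),
      w_N = stats::runif(length(residues), 103, 131),
      height = mean_height * exp(stats::rnorm(length(residues), 0, 0.3)))
  })
}

#' Simulate a titration pair of HSQC peak lists
#'
#' Produces the (free, bound) pair a single-point titration yields: listed
#' residues are shifted in 1H/15N and/or attenuated in height in the bound
#' list; everything else is unchanged up to peak-height noise. Chemical
#' shift positions are left noise-free (peak centers are fitted quantities
#' whose uncertainty is far below the perturbations of interest).
#'
#' @param base A `peak_list` (the free-state list).
#' @param shifted_residues Data frame with columns `residue`, `delta_H`,
#'   `delta_N` (ppm) or `NULL`.
#' @param attenuated_residues Data frame with columns `residue`, `ratio`
#'   (bound/free height) or `NULL`.
#' @param noise A [noise_spec()]; Gaussian height noise, sd relative to each
#'   peak's free height.
#' @return List with elements `free` and `bound` (both `peak_list`).
#' @examples
#' base <- synthetic_hsqc_peaklist(1:30)
#' simulate_titration_peaklists(base,
#'   shifted_residues = data.frame(residue = 5, delta_H = .1, delta_N = .5))
#' @export
simulate_titration_peaklists <- function(base, shifted_residues = NULL,
                                         attenuated_residues = NULL,
                                         noise = noise_spec()) {
  stopifnot(inherits(base, "peak_list"))
  bound <- base
  for (map in list(shifted_residues, attenuated_residues)) {
    if (!is.null(map) && !all(map$residue %in% base$residue))
      abort_field("residue", "perturbation map names residues absent from base")
  }
  if (!is.null(shifted_residues) && nrow(shifted_residues)) {
    i <- match(shifted_residues$residue, bound$residue)
    bound$w_H[i] <- bound$w_H[i] + shifted_residues$delta_H
    bound$w_N[i] <- bound$w_N[i] + shifted_residues$delta_N
  }
  if (!is.null(attenuated_residues) && nrow(attenuated_residues)) {
    i <- match(attenuated_residues$residue, bound$residue)
    bound$height[i] <- bound$height[i] * attenuated_residues$ratio
  }
  n <- nrow(bound)
  bound$height <- with_noise_seed(noise,
    bound$height + stats::rnorm(n, 0, noise$intensity_sd * base$height))
  list(free = base, bound = bound)
}

# Uniform random rotation matrix from a normalized quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Simulate a multi-model structural ensemble
#'
#' Each model is the template plus isotropic Gaussian displacement of sd
#' `coord_sd` per atom coordinate, followed by a random rigid-body rotation
#' and translation (so that downstream superposition is genuinely
#' exercised).
#'
#' All coordinate scatter is drawn before any rigid-body move, so the same
#' seed with `rigid_motion = FALSE` yields exactly the un-rotated copies of
#' the models -- the natural reference for superposition-free checks.
#'
#' @param template An `ensemble` with a single model (see [ensemble()]).
#' @param n_models Number of models to generate (>= 2).
#' @param coord_sd Per-coordinate Gaussian scatter, Angstrom.
#' @param noise A [noise_spec()] (its seed controls scatter and rigid moves).
#' @param rigid_motion Apply a random rotation/translation per model
#'   (default `TRUE`).
#' @return An `ensemble` with `n_models` models.
#' @examples
#' tmpl <- synthetic_template_structure(10)
#' simulate_ensemble(tmpl, 5, coord_sd = 0.5, noise = noise_spec(seed = 2))
#' @export
simulate_ensemble <- function(template, n_models, coord_sd = 0.5,
                              noise = noise_spec(), rigid_motion = TRUE) {
  stopifnot(inherits(template, "ensemble"))
  if (n_models < 2L) abort_field("n_models", "must be >= 2")
  check_number(coord_sd, "coord_sd", lower = 0)
  base <- template$coords[, , 1]
  n_atoms <- nrow(base)
  coords <- with_noise_seed(noise, {
    out <- array(0, dim = c(n_atoms, 3, n_models))
    for (m in seq_len(n_models))
      out[, , m] <- base + matrix(stats::rnorm(3 * n_atoms, 0, coord_sd),
                                  ncol = 3)
    if (rigid_motion) {
      for (m in seq_len(n_models)) {
        R <- random_rotation()
        shift <- stats::rnorm(3, 0, 5)
        out[, , m] <- sweep(out[, , m] %*% t(R), 2, shift, "+")
      }
    }
    out
  })
  ensemble(template$atoms, coords)
}

#' Synthetic single-model template structure
#'
#' Idealized alpha-helical backbone (N, CA, C, O, CB plus an amide H so
#' hydrogen filtering can be exercised), used as the template for
#' [simulate_ensemble()].
#'
#' @param n_residues Number of residues.
#' @param chain Chain identifier.
#' @return An `ensemble` with one model.
#' @export
synthetic_template_structure <- function(n_residues = 20, chain = "A") {
  atom_names <- c("N", "H", "CA", "CB", "C", "O")
  offsets <- rbind(N = c(0, 0, 0), H = c(-0.5, -0.8, 0),
                   CA = c(1.2, 0.6, 0.3), CB = c(1.6, 1.9, 0.6),
                   C = c(2.4, -0.2, 0.8), O = c(2.6, -1.4, 0.9))
  rows <- list(); xyz <- list()
  for (r in seq_len(n_residues)) {
    theta <- r * 100 * pi / 180
    origin <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * r)
    for (a in atom_names) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = r, resname = "ALA", atom = a,
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- origin + offsets[a, ]
    }
  }
  atoms <- do.call(rbind, rows)
  coords <- array(t(do.call(rbind, xyz)), dim = c(3, nrow(atoms), 1))
  coords <- aperm(coords, c(2, 1, 3))
  ensemble(atoms, coords)
}
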