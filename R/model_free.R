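#' Model-free parameter set for a single residue
#'
#' Ground-truth motional parameters for the synthetic-data generator, in the
#' Lipari-Szabo model-free parameterization: generalized order parameter
#' `S2`, overall rotational correlation time `tau_c` (ns), effective internal
#' correlation time `tau_e` (ps) and a conformational-exchange contribution
#' `Rex` (s^-1) that enters transverse relaxation additively.
#'
#' @param residue_id Integer residue number.
#' @param S2 Order parameter in `[0, 1]`.
#' @param tau_c Overall correlation time, ns (> 0).
#' @param tau_e Internal correlation time, ps (>= 0).
#' @param Rex Exchange broadening, s^-1 (>= 0).
#' @return An object of class `model_free_params`.
#' @examples
#' model_free_params(1, S2 = 0.85, tau_c = 10, tau_e = 50)
#' @export
model_free_params <- function(residue_id = 1L, S2 = 0.85, tau_c = 10,
                              tau_e = 50, Rex = 0) {
  check_number(S2, "S2", lower = 0, upper = 1)
  check_number(tau_c, "tau_c", lower = 0, allow_equal = FALSE)
  check_number(tau_e, "tau_e", lower = 0)
  check_number(Rex, "Rex", lower = 0)
  structure(list(residue_id = as.integer(residue_id), S2 = S2,
                 tau_c = tau_c, tau_e = tau_e, Rex = Rex),
            class = "model_free_params")
}

#' Lipari-Szabo model-free spectral density
#'
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{(1-S^2)\tau}{1+(\omega\tau)^2}\right], \quad
#'   \tau^{-1} = \tau_c^{-1} + \tau_e^{-1}}
#'
#' When `S2 = 1` (or `tau_e = 0`) the internal-motion term vanishes and the
#' density reduces to the rigid-rotor Lorentzian.
#'
#' @param params A [model_free_params()] object.
#' @param omega Angular frequency (rad/s); vectorized.
#' @return Spectral density in s/rad, same length as `omega`.
#' @examples
#' p <- model_free_params(1, S2 = 1, tau_c = 10)
#' model_free_J(p, 0)  # 2/5 * 10 ns = 4e-9 s/rad
#' @export
model_free_J <- function(params, omega) {
  stopifnot(inherits(params, "model_free_params"))
  tc <- params$tau_c * 1e-9
  rigid <- params$S2 * tc / (1 + (omega * tc)^2)
  internal <- 0
  if (params$tau_e > 0 && params$S2 < 1) {
    te <- params$tau_e * 1e-12
    tau <- 1 / (1 / tc + 1 / te)
    internal <- (1 - params$S2) * tau / (1 + (omega * tau)^2)
  }
  0.4 * (rigid + internal)
}

#' Forward-simulate 15N relaxation observables from model-free parameters
#'
#' Evaluates the standard dipolar + CSA expressions for amide 15N
#' relaxation at the given field:
#' \deqn{R_1 = \frac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \frac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] +
#'   \frac{c^2}{6}[4J(0) + 3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + \frac{d^2}{4R_1}\frac{\gamma_H}{\gamma_N}
#'   [6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]}
#' With the signed gyromagnetic ratio of 15N, slow-tumbling residues give
#' NOE < 1 and the extreme-narrowing limit is strongly negative.
#'
#' @param params A [model_free_params()] object.
#' @param ctx A [spectrometer_context()].
#' @return Named list with `R1`, `R2` (s^-1) and `NOE` (dimensionless).
#' @examples
#' forward_relaxation(model_free_params(1, S2 = 1, tau_c = 10),
#'                    spectrometer_context(800))
#' @export
forward_relaxation <- function(params, ctx) {
  stopifnot(inherits(ctx, "spectrometer_context"))
  J <- function(w) model_free_J(params, w)
  wH <- ctx$omega_H; wN <- ctx$omega_N
  d2 <- ctx$d^2; c2 <- ctx$c^2
  R1 <- d2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                  6 * J(wH + wN)) +
        c2 / 6 * (4 * J(0) + 3 * J(wN)) + params$Rex
  NOE <- 1 + d2 / (4 * R1) * (ctx$gamma_H / ctx$gamma_N) *
    (6 * J(wH + wN) - J(wH - wN))
  list(R1 = R1, R2 = R2, NOE = NOE)
}
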