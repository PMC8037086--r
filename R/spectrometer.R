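# Physical constants (SI). Gyromagnetic ratios are signed: gamma_N < 0 for
# 15N, which carries through to the sign conventions of the cross-relaxation
# rate and the heteronuclear NOE.
.MU0 <- 4 * pi * 1e-7          # vacuum permeability, T m / A
.PLANCK <- 6.62607015e-34      # Planck constant, J s
.GAMMA_H <- 2.6752218744e8     # 1H gyromagnetic ratio, rad s^-1 T^-1
.GAMMA_N <- -2.7126e7          # 15N gyromagnetic ratio, rad s^-1 T^-1

#' Spectrometer context for 15N relaxation analysis
#'
#' Resolves the field-dependent quantities entering the relaxation rate
#' expressions and the reduced spectral density mapping: the 1H and 15N
#' Larmor frequencies, the dipolar interaction constant
#' \eqn{d = \mu_0 h \gamma_H \gamma_N \langle r_{NH}^{-3}\rangle / (8\pi^2)}
#' and the chemical-shift-anisotropy constant
#' \eqn{c = \omega_N \Delta\sigma / \sqrt{3}}.
#'
#' Frequencies `omega_H` and `omega_N` are stored as magnitudes (rad/s) for
#' use as spectral-density arguments; the signed ratio `gamma_N / gamma_H`
#' is used wherever the sign convention matters (cross-relaxation, NOE).
#'
#' @param proton_frequency Proton Larmor frequency in MHz (default 800, the
#'   field used for the relaxation measurements).
#' @param r_NH Amide N-H bond length in Angstrom (default 1.02).
#' @param delta_sigma 15N chemical shift anisotropy in ppm (default -160).
#' @param gamma_H,gamma_N Gyromagnetic ratios in rad s^-1 T^-1 (signed).
#' @return An object of class `spectrometer_context` with elements
#'   `omega_H`, `omega_N` (rad/s, magnitudes), `d`, `c` (s^-1 per (s/rad)
#'   of spectral density, i.e. `d^2 * J` has units s^-1), and the inputs.
#' @examples
#' ctx <- spectrometer_context(800)
#' ctx$omega_N / (2 * pi) / 1e6  # 15N frequency, MHz
#' @export
spectrometer_context <- function(proton_frequency = 800,
                                 r_NH = 1.02,
                                 delta_sigma = -160,
                                 gamma_H = .GAMMA_H,
                                 gamma_N = .GAMMA_N) {
  check_number(proton_frequency, "proton_frequency", lower = 0,
               allow_equal = FALSE)
  check_number(r_NH, "r_NH", lower = 0, allow_equal = FALSE)
  check_number(delta_sigma, "delta_sigma")
  omega_H <- 2 * pi * proton_frequency * 1e6
  omega_N <- omega_H * abs(gamma_N / gamma_H)
  r_m <- r_NH * 1e-10
  d <- .MU0 * .PLANCK * gamma_H * gamma_N / (8 * pi^2 * r_m^3)
  c_csa <- omega_N * delta_sigma * 1e-6 / sqrt(3)
  structure(list(proton_frequency = proton_frequency,
                 gamma_H = gamma_H, gamma_N = gamma_N,
                 r_NH = r_NH, delta_sigma = delta_sigma,
                 omega_H = omega_H, omega_N = omega_N,
                 d = d, c = c_csa),
            class = "spectrometer_context")
}

#' @export
print.spectrometer_context <- function(x, ...) {
  cat(sprintf("<spectrometer_context> %g MHz 1H (%.2f MHz 15N)\n",
              x$proton_frequency, x$omega_N / 2 / pi / 1e6))
  cat(sprintf("  r_NH %.3f A, delta_sigma %g ppm, d %.4g, c %.4g\n",
              x$r_NH, x$delta_sigma, x$d, x$c))
  invisible(x)
}
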