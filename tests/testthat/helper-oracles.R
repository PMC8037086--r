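# Independent brute-force oracles, coded separately from the package
# implementation (written first; the package is checked against these,
# never the other way round).

# Lipari-Szabo spectral density by direct formula evaluation.
# tau_c, tau_e in SECONDS here (the package takes ns/ps).
oracle_J <- function(S2, tau_c, tau_e, omega) {
  t1 <- S2 * tau_c / (1 + (omega * tau_c)^2)
  t2 <- 0
  if (tau_e > 0) {
    tau <- 1 / (1 / tau_c + 1 / tau_e)
    t2 <- (1 - S2) * tau / (1 + (omega * tau)^2)
  }
  0.4 * (t1 + t2)
}

# Direct evaluation of the dipolar + CSA relaxation expressions.
oracle_rates <- function(S2, tau_c, tau_e, Rex, freq_mhz = 800,
                         gH = 2.6752218744e8, gN = -2.7126e7,
                         rNH = 1.02e-10, dsig = -160e-6) {
  mu0 <- 4 * pi * 1e-7; h <- 6.62607015e-34
  wH <- 2 * pi * freq_mhz * 1e6
  wN <- wH * abs(gN / gH)
  d <- mu0 * h * gH * gN / (8 * pi^2 * rNH^3)
  cc <- wN * dsig / sqrt(3)
  J <- function(w) oracle_J(S2, tau_c, tau_e, w)
  R1 <- d^2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + cc^2 * J(wN)
  R2 <- d^2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                   6 * J(wH + wN)) +
        cc^2 / 6 * (4 * J(0) + 3 * J(wN)) + Rex
  NOE <- 1 + d^2 / (4 * R1) * (gH / gN) * (6 * J(wH + wN) - J(wH - wN))
  list(R1 = R1, R2 = R2, NOE = NOE, d = d, c = cc)
}

# Brute-force rotational superposition: random quaternion search plus
# Nelder-Mead polish on the quaternion, entirely independent of the
# SVD-based implementation.
oracle_superpose_rmsd <- function(mobile, reference, n_search = 4000) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot_from_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- rot_from_q(q)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best_q <- NULL; best <- Inf
  for (i in seq_len(n_search)) {
    q <- stats::rnorm(4)
    v <- obj(q)
    if (v < best) { best <- v; best_q <- q }
  }
  for (k in 1:3) {
    op <- stats::optim(best_q, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
    best_q <- op$par; best <- op$value
  }
  best
}

# Per-model RMSD to the plain (superposition-free) mean of un-rotated
# model copies.
oracle_rmsd_no_superposition <- function(coords, idx) {
  nm <- dim(coords)[3]
  mean_xyz <- apply(coords, c(1, 2), mean)
  vapply(seq_len(nm), function(m)
    sqrt(mean(rowSums((coords[idx, , m] - mean_xyz[idx, ])^2))),
    numeric(1))
}

# Shared small fixtures -------------------------------------------------

ctx800 <- function() spectrometer_context(800)

random_mf_params <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      model_free_params(i,
        S2 = stats::runif(1, 0, 1),
        tau_c = stats::runif(1, 1, 20),
        tau_e = stats::runif(1, 0, 200),
        Rex = stats::runif(1, 0, 6)))
  })
}
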