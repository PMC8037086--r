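#!/usr/bin/env Rscript
# Reduced spectral density mapping of the fitted rates: per-residue J(0),
# J(wN), J(0.87wH) with Monte-Carlo errors, and the per-domain mean J(0)
# comparison (the slow-motion readout distinguishing the two domains).

library(ahadyn)

ctx <- spectrometer_context(800)   # -160 ppm CSA, 1.02 A N-H bond
rates <- read_rates_csv("results/rates.csv")

prof <- propagate_errors(rates, ctx, n_mc = 500, seed = 11L)
utils::write.csv(prof, "results/spectral_densities.csv", row.names = FALSE)

nterm <- summarize_region(prof, c(28, 162))
cterm <- summarize_region(prof, c(204, 335))
summary <- data.frame(
  region = c("Nterm (28-162)", "Cterm (204-335)"),
  mean_J0 = c(nterm$mean, cterm$mean),
  sem_J0 = c(nterm$sem, cterm$sem),
  n = c(nterm$n, cterm$n))
utils::write.csv(summary, "results/j0_region_summary.csv",
                 row.names = FALSE)

cat(sprintf("mean J(0) N-domain: %.2f +/- %.2f ns/rad (n = %d)\n",
            nterm$mean, nterm$sem, nterm$n))
cat(sprintf("mean J(0) C-domain: %.2f +/- %.2f ns/rad (n = %d)\n",
            cterm$mean, cterm$sem, cterm$n))
if (nterm$mean > cterm$mean) {
  cat("the exchange-rich N-domain shows the larger mean J(0),",
      "as its Rex/tau_c ground truth dictates\n")
} else {
  cat("WARNING: unexpected J(0) ordering between domains\n")
}
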