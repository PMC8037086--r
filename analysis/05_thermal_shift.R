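#!/usr/bin/env Rscript
# Boltzmann fits of the replicate melt curves, per-construct Tm (mean +/-
# sd over 3 replicates) and the delta-Tm matrix between constructs.

library(ahadyn)

tbl <- read_melt_csv("results/data/melt_curves.csv")
fits <- fit_melt_table(tbl)

tm_tab <- data.frame(
  construct = names(fits),
  Tm = vapply(fits, `[[`, numeric(1), "Tm"),
  Tm_sd = vapply(fits, `[[`, numeric(1), "Tm_error"),
  slope = vapply(fits, `[[`, numeric(1), "slope"))
utils::write.csv(tm_tab, "results/tm_fits.csv", row.names = FALSE)
print(tm_tab, row.names = FALSE, digits = 4)

cons <- names(fits)
dmat <- outer(seq_along(cons), seq_along(cons), Vectorize(function(i, j)
  delta_tm(fits[[i]], fits[[j]])$delta_Tm))
dimnames(dmat) <- list(cons, cons)
utils::write.csv(round(dmat, 3), "results/delta_tm_matrix.csv")

d1 <- delta_tm(fits[["1-338"]], fits[["28-338"]])
d2 <- delta_tm(fits[["28-338"]], fits[["28-335"]])
cat(sprintf("\ndelta Tm (1-338 vs 28-338): %.2f +/- %.2f degC\n",
            d1$delta_Tm, d1$error))
cat(sprintf("delta Tm (28-338 vs 28-335): %.2f +/- %.2f degC\n",
            d2$delta_Tm, d2$error))
cat("full matrix in results/delta_tm_matrix.csv\n")
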