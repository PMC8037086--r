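# ahadyn

Solution-NMR dynamics, thermal stability and ensemble statistics for the
human Hsp90 co-chaperone Aha1 — as a tested, reusable R pipeline.

Aha1 is the only co-chaperone known to strongly stimulate Hsp90's ATPase
cycle, and its two domains behave very differently in solution: the
N-terminal domain is marginally stable and rich in slow (µs–ms)
conformational exchange, while the C-terminal domain is thermostable and
dominated by faster (ps–ns) motions. Quantifying that contrast takes a
chain of standard but fiddly analyses, which this package implements
end-to-end:

* **Relaxation fitting** — per-residue ¹⁵N R₁/R₂ from single-exponential
  decays, I(t) = I₀·e^(−Rt), with Monte-Carlo rate errors and
  duplicate-spectra noise estimation; heteronuclear NOE (XNOE) ratios with
  propagated errors.
* **Reduced spectral density mapping** — σ = R₁(NOE−1)γN/γH, then
  J(ωN) = (4R₁−5σ)/(3d²+4c²), J(0) = (6R₂−3R₁−2.72σ)/(3d²+4c²),
  J(0.87ωH) = 4σ/(5d²), with Monte-Carlo error propagation and per-domain
  J(0) summaries.
* **HSQC titration analysis** — combined CSP
  √(Δδ_H² + (0.14·Δδ_N)²), robust significance thresholds, and
  height-ratio attenuation analysis for comparing binding between
  constructs.
* **Thermal shift fitting** — Boltzmann sigmoid
  F(T) = LL + (UL−LL)/(1+e^((Tm−T)/a)) on truncated melt curves, replicate
  aggregation, and ΔTm between constructs.
* **Ensemble statistics** — iterative mean-structure RMSD of multi-model
  PDB ensembles (Kabsch superposition) and NOE-restraint counts by
  sequence separation (intra / sequential / medium / long).
* **Synthetic-data generation** — every input above can be generated from
  known ground truth (Lipari–Szabo model-free relaxation, Boltzmann melts,
  planted perturbations, coordinate scatter), making each stage a
  parameter-recovery test.

## Worked example

```r
library(ahadyn)

# thermal stability of two constructs, three replicates each, 1% noise
fits <- lapply(1:3, function(i)
  fit_boltzmann(simulate_melt_curve(72.41, 1.5, noise = noise_spec(0.01, i),
                                    construct_label = "C-domain")))
agg <- aggregate_replicates(fits)
agg
#> <boltzmann_fit> C-domain: Tm 72.41 degC (slope 1.50, window 31.5-98.0)

# relaxation -> reduced spectral densities for one residue
ctx <- spectrometer_context(800)          # 800 MHz, -160 ppm CSA, 1.02 A
p   <- model_free_params(50, S2 = 0.85, tau_c = 10, tau_e = 50, Rex = 2)
r   <- forward_relaxation(p, ctx)         # ground-truth R1, R2, NOE
map_profile(data.frame(residue = 50, R1 = r$R1, R2 = r$R2, NOE = r$NOE), ctx)
#>   residue      sigma       J0      JwN         JwH   ok
#> 1      50 0.02443428 3.894673 0.129933 0.003758782 TRUE
```

The mapped J(0) of 3.90 ns/rad decomposes into the model-free
J(0) = 0.4·S²·τc ≈ 3.40 ns/rad plus the exact exchange offset
6·Rex/(3d²+4c²) ≈ 0.49 ns/rad: slow exchange inflates J(0), which is the
readout that separates the two domains. J(0.87ωH) is small and positive, as
expected for a folded residue (NOE < 1 ⇒ σ > 0).

The `analysis/` directory holds the full workflow as numbered drivers —
`01_simulate_inputs.R` through `06_ensemble_stats.R` generate all inputs
from ground truth and write fitted rates, spectral densities, CSP tables,
Tm/ΔTm tables and ensemble statistics under `results/`;
`07_deposited.R` (network required) downloads the deposited ensembles and
restraint list and compares backbone/heavy RMSD-from-mean and long-range
restraint counts against the published table.

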