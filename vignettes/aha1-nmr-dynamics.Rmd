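---
title: "Methods: NMR dynamics, stability and ensemble statistics for Aha1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR dynamics, stability and ensemble statistics for Aha1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahadyn)
```

`ahadyn` re-implements, as a tested and reusable pipeline, the quantitative
analysis chain used to characterize the solution behavior of the human Hsp90
co-chaperone Aha1: backbone ¹⁵N relaxation fitting, reduced spectral density
mapping, HSQC titration (chemical-shift-perturbation and attenuation)
analysis, thermal-shift Tm fitting, and multi-model ensemble/restraint
statistics. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Why a synthetic-data generator is first-class here

The raw spectra, per-residue peak heights and fitted relaxation rates behind
the original study are not publicly deposited; only the structural ensembles
and headline numbers are. Every analysis stage in this package is therefore
validated by *parameter recovery*: the generator produces each input from
known ground truth (model-free parameters, melting temperatures, planted
perturbations, coordinate scatter), the truth is retained next to the data,
and the downstream stage must recover it. The generator is tested code, not
a fixture.

What it emulates: single-exponential decay series on the published delay
grids with additive Gaussian peak-height noise; duplicate spectra for error
estimation; saturated/unsaturated XNOE height pairs; Boltzmann-sigmoid melt
curves on the 25–99 °C ramp; assigned peak lists with controlled shifts and
attenuations; small multi-model ensembles with isotropic coordinate scatter
plus random rigid-body motion. What it does not emulate: spectral-level
artifacts (peak overlap, baseline distortion, apodization), deuteration
effects on relaxation, peak-position noise in titrations (peak centers are
fitted quantities whose uncertainty is far below the perturbations of
interest), correlated noise between delays, and anisotropic tumbling.
Passing recovery tests therefore demonstrates correctness of the estimators
under their stated noise model, not robustness to every pathology of real
spectra.

## Relaxation rate fitting

Each residue's intensity series is fitted to the two-parameter model
$I(t) = I_0 e^{-Rt}$ ("single-exponential decay", no baseline offset) by
Levenberg–Marquardt (`minpack.lm::nlsLM`), started from the log-linear
slope of $\ln I$ vs $t$. With noiseless input the chain
simulate → fit is an identity on $(I_0, R)$ to better than $10^{-9}$
relative error. Per-residue failures (non-convergence, non-positive rate,
constant intensities) become flagged records and are excluded downstream
rather than aborting a run.

Uncertainties follow the Monte-Carlo convention: the best-fit curve is
perturbed `n_mc` times (default 500) with Gaussian noise at the
duplicate-derived level, refitted, and the standard deviation of the
refitted rates is reported (sd, not sem — the convention chosen here for
all "±" values). The duplicate noise estimator is
$\hat\sigma = \mathrm{sd}(I_a - I_b)/\sqrt{2}$. XNOE values are ratios of
saturated to unsaturated peak heights with first-order ratio error
propagation from the duplicate-derived height noise.

Default delay grids are the published ones (T1: 10–2560 ms in ten steps;
T2: 10–150 ms in eight steps for the two-domain construct, with the
single-domain variants also provided). The default intensity noise of the
generator (1% of the reference height) is a placeholder chosen as typical
of well-resolved HSQC-detected experiments — the study does not state its
noise level — and recovery tolerances in the tests are computed from the
generated noise, not tuned to it.

## Reduced spectral density mapping

With $\sigma = R_1(\mathrm{NOE}-1)\gamma_N/\gamma_H$ (signed ratios,
$\gamma_N < 0$, so NOE < 1 gives $\sigma > 0$), the mapping implemented is

$$J(\omega_N) = \frac{4R_1 - 5\sigma}{3d^2 + 4c^2},\qquad
  J(0) = \frac{6R_2 - 3R_1 - 2.72\sigma}{3d^2 + 4c^2},\qquad
  J(0.87\omega_H) = \frac{4\sigma}{5d^2},$$

with $d = \mu_0 h \gamma_H\gamma_N \langle r_{NH}^{-3}\rangle/(8\pi^2)$ and
$c = \omega_N\Delta\sigma/\sqrt{3}$. Three deliberate choices:

* The dipolar constant is implemented as the standard *product*
  $\gamma_H\gamma_N$; the source text prints it as a ratio, which is
  dimensionally inconsistent and is read as a typesetting artifact.
* The $J(\omega_N)$ coefficient is 5 as printed; the common literature
  variant 5.6 is available via `jwn_variant = "literature"` but is not the
  default, preferring fidelity to the printed equations.
* $r_{NH} = 1.02$ Å (standard amide bond length; unstated in the source)
  and $\Delta\sigma = -160$ ppm, at a default field of 800 MHz. Frequencies
  are carried as magnitudes; the sign of $\gamma_N$ enters only through
  $\sigma$ and the NOE.

J errors are propagated by Monte Carlo (independent Gaussians on
$R_1, R_2,$ NOE; default 500 draws; deterministic under a seed), which at
small errors agrees with first-order analytic propagation to within 10%.

**Accuracy of the high-frequency arm.** The mapping assumes the spectral
density is flat near $\omega_H$. The identity
$6J(\omega_H+\omega_N) - J(\omega_H-\omega_N) = 5J(0.87\omega_H)$ is exact
for a flat density, but for a pure rigid rotor ($S^2 = 1$) the left side
effectively probes $\approx 1.16\,\omega_H$, so the mapped
$J(0.87\omega_H)$ under-estimates the true value by a factor approaching
$(0.87/1.16)^2 \approx 0.56$. Measured against the model-free generator at
800 MHz with $\tau_e = 50$ ps: mapped/true ≈ 0.56 at $S^2 = 1$, 0.81 at
$S^2 = 0.85$, 0.91 at $S^2 = 0.7$. The package's tests therefore assert
10% recovery of $J(0.87\omega_H)$ only where fast internal motions dominate
the high-frequency density, and a verified systematic envelope elsewhere;
$J(0)$ is recovered within 10% across the whole grid (with the exact
$6R_{ex}/(3d^2+4c^2)$ offset accounted for when exchange is present). This
is an intrinsic property of reduced spectral density mapping, not an
implementation artifact.

The model-free generator itself uses the Lipari–Szabo form with order
parameter $S^2$, overall tumbling $\tau_c$ and internal time $\tau_e$
($1/\tau = 1/\tau_c + 1/\tau_e$); it exists to *generate* data, and no
model-free fitting of experimental data is attempted. Synthetic-domain
defaults in the analysis scripts ($\tau_c$ 8–12 ns, $S^2$ 0.85–0.88,
$\tau_e$ 40–50 ps, Rex 0–3.5 s⁻¹) are plausible for ~15 kDa domains at
25 °C; they are not a reconstruction of the experimental protein (whose
mean $J(0)$ values indicate slower effective tumbling), so regional $J(0)$
summaries reproduce the published *ordering* between domains, not the
published magnitudes.

## HSQC titration analysis

Peak lists are paired by assignment label; residues missing from the bound
list are flagged (broadened beyond detection). The combined CSP is
$\sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$ — formula and weight
are the field convention, as the source does not state its criterion, and
the weight is configurable. Significance thresholding is a design choice:
the 10%-trimmed mean plus one 10%-trimmed sd of the CSP distribution
(robust to a perturbed minority), with strict inequality so a degenerate
all-equal distribution flags nothing. Attenuation analysis uses
bound/free height ratios normalized by their median — absorbing
concentration and receiver-gain differences between spectra, under the
assumption that most residues are unaffected; when a majority is
attenuated, the normalized values understate the effect (the analysis
driver shows the unnormalized variant for that regime). Ratios below 0.5
(configurable) are flagged, and the flagged fraction is the
global-attenuation readout used to compare systems. The published
perturbed-residue lists depend on the unreleased spectra and are
documentation targets only.

## Thermal shift fitting

Melt curves are truncated to the window from the pre-transition
fluorescence minimum to the global maximum before fitting — SYPRO-orange
curves decay after the transition as dye partitions out of aggregates, and
the windowing rule is a choice the source omits. The Boltzmann sigmoid
$F(T) = LL + (UL-LL)/(1+e^{(T_m-T)/a})$ is fitted by Levenberg–Marquardt
with the initial $T_m$ at the maximum first difference. $T_m$ is invariant
to affine rescaling of fluorescence and equivariant under temperature
shifts, and equals the fitted sigmoid's inflection point analytically.
Replicates (three, per the assay protocol) aggregate as mean ± sd (sem
behind a flag). Raw (not baseline-corrected) fluorescence is fitted; the
truncation window makes the distinction immaterial for clean sigmoids. The
generator's default grid is 25–99 °C at 0.5 °C — the ramp endpoints are
stated by the assay protocol, the sampling density is not.

## Ensemble and restraint statistics

`rmsd_from_mean()` implements the explicit-mean convention: superpose all
models on model 1 over the selection, average, re-superpose on the running
mean, and iterate until the mean moves ≤ 10⁻⁶ Å (≤ 100 iterations);
per-model RMSDs to the converged mean are reported as mean ± sd.
Superposition is a proper-rotation (det +1) least-squares fit via SVD
(Kabsch), applied to all atoms, computed over the selection; it is
cross-checked in the tests against both a brute-force quaternion search
and an independent library implementation. Backbone means N, CA, C (the
common NMR-table convention; carbonyl O available behind `include_O`),
heavy means all non-hydrogens. Because the deposited tables do not state
their atom set or convention, comparisons against published RMSDs carry a
±0.1 Å tolerance.

Restraints classify purely by sequence separation (0 intra, 1 sequential,
2–4 medium, >4 long), symmetric in $(i,j)$, counts partitioning the total.
The permissive `.mr` reader extracts the first residue of each top-level
selection in XPLOR `assign` statements, counting ambiguous OR-group
restraints once (logged); whether the published totals count them once or
per-alternative is unknowable from the table alone.

The multi-model PDB reader parses each MODEL block, resolves alternate
locations to the first copy, and harmonizes the roster by dropping (with a
message) atoms absent from any model. The deposited-ensemble comparisons
themselves require downloading PDB 7DMD/7DME and the restraint file
(`analysis/07_deposited.R`); the rest of the pipeline and tests are fully
offline.

## Problem sizes and determinism

All randomness flows through integer seeds (`noise_spec`, or explicit
`seed` arguments), and identical seeds reproduce outputs bit for bit. The
shipped analyses use 89 residues × 2 duplicates × 2 experiments of decay
series, 500-draw Monte-Carlo error propagation, 3 melt replicates × 5
constructs, 120-residue titration lists and a 20-model ensemble — sizes
chosen so a full run completes in well under a minute while keeping
recovery standard errors far below the tested tolerances.

## Known limitations

* Exchange (Rex) is generated and its exact algebraic effect on $J(0)$ is
  tested, but no exchange-model fitting or CPMG-style dispersion analysis
  is provided.
* Isotropic tumbling only; no diffusion-tensor analysis.
* The titration module handles single-point titrations (the 10:1
  experiment design), not multi-point tracking or $K_d$ fitting.
* The thermal-shift module extracts $T_m$ only; no ΔH/ΔG two-state
  thermodynamics.
* The $J(0.87\omega_H)$ systematic bias discussed above is inherited from
  the reduced-mapping equations themselves.
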