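Package: ahadyn
Title: NMR Dynamics, Stability and Ensemble Statistics for Human Aha1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable analysis chain for solution-NMR characterization of the
    Hsp90 co-chaperone Aha1: single-exponential fitting of 15N T1/T2
    relaxation series with Monte-Carlo errors, heteronuclear NOE ratios with
    duplicate-based errors, reduced spectral density mapping to J(0), J(wN)
    and J(0.87wH), HSQC chemical-shift-perturbation and intensity-attenuation
    analysis of titration peak lists, Boltzmann-sigmoid melting-temperature
    fitting of thermal shift assay curves, and multi-model ensemble
    RMSD-from-mean and NOE-restraint statistics. A synthetic-data generator
    built on the Lipari-Szabo model-free spectral density provides
    ground-truth inputs for parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
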