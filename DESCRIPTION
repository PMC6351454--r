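Package: emtmac
Title: Crosstalk Between Tumor-Cell EMT Plasticity and Macrophage Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation co-culture models of the interplay
    between epithelial-mesenchymal plasticity of cancer cells and M1/M2
    polarization of tumor-associated macrophages. Provides three nested model
    variants (macrophage polarization only; cancer-enhanced M1/M2
    interconversion; apoptosis-mediated M1-to-M2 conversion with an
    apoptotic-factor compartment), steady-state solvers (a semi-analytic
    branch construction for the conservation-constrained variant and
    multi-start damped Newton iteration otherwise), eigenvalue-based
    stability classification with Hopf and fold indicators, parameter sweeps
    with bisection for critical points such as cancer-extinction thresholds,
    and a per-gene EMT-score association stage (Pearson correlation,
    median-split two-sample testing, gene-set enrichment counts) driven by a
    seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
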