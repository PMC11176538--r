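Package: mmcdose
Title: Tumor-Immune Dynamics and Dose Determination for Intravesical
    Mitomycin-C Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-compartment ordinary differential equation
    model of non-muscle-invasive bladder cancer under continuous intravesical
    mitomycin-C instillation: drug amount, tumor cells and effector (immune)
    cells.  Provides the model right-hand side and Jacobian, adaptive
    Runge-Kutta integration, closed-form disease-free equilibria with local
    stability criteria, numerical cancer equilibria, tumor diameter to
    cell-count geometry, dose and half-life unit arithmetic, a personalized
    dose-determination algorithm with patient classification, a seeded
    virtual-patient cohort experiment, Latin hypercube sampling with partial
    rank correlation (PRCC) global sensitivity analysis, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
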