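Package: salmosim
Title: Simulation of Salmonella-Based Cancer Immunotherapy Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An eight-compartment ordinary differential equation model of
    antigen-delivering Salmonella cancer therapy, coupling bacterial
    pharmacokinetics (blood and intratumoral compartments), logistic tumor
    growth with intracellular invasion, two effector T cell pools with
    saturating activation and killing, and inflammatory cytokine dynamics.
    Provides a stiff-capable simulator with closed-form oracles for limiting
    cases, trajectory summary metrics (peaks, areas under the curve,
    threshold-crossing times, invaded fractions), a declarative scenario
    engine covering administration route, hot and cold immune
    microenvironments, dose-by-tumor-size grids and strain-engineering
    parameter sweeps, and a Latin hypercube sampling / partial rank
    correlation coefficient global sensitivity module. A command-line front
    end runs scenarios and sensitivity analyses from configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
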