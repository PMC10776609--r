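Package: jetcryst
Title: Reduced-Order Simulation of Continuous Anti-Solvent Crystallization
    in Impinging-Jet Crystallizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates continuous anti-solvent crystallization of lovastatin
    from methanol solution with water as anti-solvent, on compartment-network
    representations of an impinging-jet crystallizer.  Couples a
    size-discretized population balance (high-resolution finite-volume
    semi-discrete central scheme with minmod-limited reconstruction), a
    three-environment presumed-PDF micromixing model, closed-form
    solubility/nucleation/growth kinetics, and a mixing/crystallization
    enthalpy balance.  Ships analytic oracles (constant-growth advection,
    MSMPR steady state), convergence and conservation audits, deterministic
    fixture generation, YAML run configuration, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
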