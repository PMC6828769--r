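Package: jeffreyflow
Title: Jeffrey-Fluid Flow in Porous-Walled Channels and Flat-Plate
    Hemodialyzers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form perturbation solution for the creeping flow of a
    Jeffrey (linear viscoelastic) fluid in a narrow channel whose walls leak
    according to Darcy's law, together with the hydrodynamic quantities
    derived from it (mean pressure drop, wall shear stress, cross-sectional
    flow rate, leakage flux, fractional reabsorption, streamlines and
    stagnation points). Includes nondimensionalization utilities for
    laboratory data, an inverse procedure that estimates the membrane
    filtration coefficient of a flat-plate hemodialyzer from its measured
    ultrafiltration rate via a truncated series solve, and independent
    numerical oracles (ODE integration and finite-difference residuals) that
    verify the closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
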