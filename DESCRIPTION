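Package: dsfddg
Title: Thermodynamic Analysis of Differential Scanning Fluorimetry and
    Toy Alchemical Free-Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses protein thermal-shift (differential scanning
    fluorimetry) melting curves under a two-state unfolding model:
    baseline estimation, fraction unfolded, van't Hoff enthalpy fitting,
    Kirchhoff heat-capacity estimation across denaturant-shifted melting
    points, Gibbs-Helmholtz stability extrapolation, and relative
    ligand-binding free energies (ddG) with first-order uncertainty
    propagation. Includes a synthetic plate generator with known ground
    truth for end-to-end validation, and a desk-scale thermodynamic
    integration module (linear coupling Hamiltonian, Metropolis sampling,
    forward/backward hysteresis balancing) validated against closed-form
    free energies of toy systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
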