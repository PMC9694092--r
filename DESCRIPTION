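Package: qgethermo
Title: Gas-Phase Thermodynamics of Flexible Molecules via the
    Quasi-Gaussian Entropy Gamma State
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parameterizes an analytic isobaric equation of state
    (chemical potential, enthalpy, entropy and heat capacity versus
    temperature) for flexible molecules and molecular complexes in the
    ideal-gas state, following the quasi-Gaussian entropy (QGE)
    diverging-Gamma-state model.  A reference conformation is located by
    essential-dynamics analysis of a conformational-sampling trajectory,
    characterized by mass-weighted normal modes, and its occupation
    probability within a +/- k sigma box on the semi-classical modes
    anchors the excess thermodynamics at a reference temperature.
    Temperature-series fits of the mean bending and residual potential
    energies supply the constant excess heat capacity.  Includes a
    seeded Metropolis torsional sampler for united-atom chain toys with
    brute-force quadrature oracles, plus readers and writers for
    multi-frame XYZ/GRO trajectories, xvg-style energy series and
    frequency tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
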