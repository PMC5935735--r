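Package: protonpath
Title: Continuum-Electrostatics pKa Shifts and Minimum-Energy Proton-Transfer Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale machinery for ranking protonation states and comparing
    proton-transfer mechanisms in enzyme active sites. Provides a
    finite-difference linearized Poisson-Boltzmann solver with a probe-defined
    molecular-surface dielectric boundary, linear-response protonation free
    energies and pKa shifts averaged over snapshot ensembles, a chain-of-states
    (elastic-band/string hybrid) minimum-energy-path optimizer with
    climbing-image saddle refinement, free-energy perturbation along fixed
    reaction paths with rigid-rotor/harmonic-oscillator vibrational
    corrections, and synthetic generators (Born ions, toy titratable sites,
    linear-response ensembles with exact answers, analytic benchmark surfaces)
    that make every stage testable against closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
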