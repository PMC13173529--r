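Package: qsci
Title: Occupancy-Guided Quantum-Selected Configuration Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classical toolkit for quantum-selected configuration
    interaction (QSCI) guided by time-evolved orbital-occupancy
    statistics.  Provides bit-level Slater determinant algebra with
    Slater-Condon matrix elements, FCIDUMP integral input/output, a
    Jordan-Wigner qubit Hamiltonian with l1-norm diagnostics, stochastic
    qDRIFT real-time evolution emulated by statevector simulation with
    computational-basis measurement sampling, occupancy-driven
    excitation sampling and screening, subspace diagonalization,
    Epstein-Nesbet second-order perturbation corrections with
    extrapolation to the zero-correction limit, and a Heatbath CI
    benchmark with a delta-halving schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
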