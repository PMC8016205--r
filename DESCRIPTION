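Package: mlccx
Title: Multilevel Coupled Cluster Excitation Energies in Reduced Orbital Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel CC2 (MLCC2) and CCS/CCSD multilevel CCSD (MLCCSD) excitation
    energies for closed-shell molecules, with the doubles cluster operator restricted to an
    active orbital space. Includes a Gaussian-basis restricted Hartree-Fock reference with a
    built-in McMurchie-Davidson integral engine, frozen-Fock reduced-space embedding, active
    orbital spaces from correlated natural transition orbitals (CNTOs) or restricted-pivot
    Cholesky occupied orbitals plus projected atomic orbitals (PAOs), and a two-step pivoted
    Cholesky factorization of the electron repulsion integrals with direct construction of the
    factors in the molecular orbital basis and optional MO screening. Shared DIIS and
    non-symmetric Davidson solvers, a run driver, and a command-line interface are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
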