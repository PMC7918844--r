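Package: dhcell
Title: Debye-Huckel Electrostatics of Discrete Charges at a Dielectric
    Interface
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-analytic linearized Poisson-Boltzmann (Debye-Huckel)
    machinery for discrete surface charges at a planar dielectric interface
    between a salt solution and a low-dielectric medium.  Computes surface
    potentials of charged disks and point charges inside a cylindrical
    Wigner-Seitz cell by Fourier-Bessel series, the isolated-disk and
    Stillinger point-charge potentials by Hankel transform with
    oscillation-aware quadrature, the screened-Coulomb plus dipole far-field
    asymptote, and the discrete-to-continuum free-energy ratio F/F0 with its
    point-charge limit, including the crossover of the scaled free energy
    from a quadratic to a 2.5-power dependence on surface charge density.
    An axisymmetric finite-difference solver of the coupled
    Debye-Huckel/Laplace problem provides independent verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
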