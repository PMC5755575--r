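Package: qcrefine
Title: Hirshfeld Atom Refinement of X-Ray Structure Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A quantum-crystallographic refinement engine. Molecular electron
    densities are partitioned into overlapping aspherical atoms by the
    Hirshfeld stockholder principle, Fourier-transformed into atomic
    scattering factors, and used in weighted least-squares refinement of
    atomic positions and anisotropic displacement parameters (hydrogens
    included) against structure-factor magnitudes, iterating density
    calculation and refinement to convergence. Includes an independent-atom
    (spherical form factor) reference mode, crystal-field point-charge and
    dipole environments, reading and writing of core CIF and SHELX hkl
    files, residual-density maps with fractal-dimension curves, the rigid-bond
    test, ADP and bond-length comparison statistics, and an analytic
    Gaussian-atom simulator providing closed-form oracles for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
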