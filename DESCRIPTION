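Package: rotspec
Title: Rotational Spectroscopy of Asymmetric Tops with Dual Nuclear
    Quadrupole Coupling and Effective (r0) Structure Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for high-resolution rotational spectra of
    near-planar asymmetric-top molecules and their hydrogen-bonded clusters.
    Implements the Watson A-reduced asymmetric-rotor Hamiltonian
    (representation Ir) with quartic and sextic centrifugal distortion,
    first-order nuclear quadrupole hyperfine structure for one or two
    spin-1 (14N) nuclei in the Itot coupling scheme, forward spectrum
    prediction with a/b-type selection rules and type-II band analysis,
    weighted global least-squares fitting of spectroscopic constants to
    mixed-accuracy line lists, quadrupole-tensor rotation, scaling and
    diagonalization for bond-axis geometry analysis, planar-moment geometry
    scaling, rigid cluster assembly from three intermolecular parameters,
    and least-squares effective (r0) structure determination from
    isotopologue moments of inertia.  Ships reference spectroscopic
    constants for 2-aminopyridine (AMP) and its 1:1 water cluster (AMW)
    together with synthetic-data generators so that every stage of the
    analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
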