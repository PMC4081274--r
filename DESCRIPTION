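Package: d3hplus
Title: Dispersion and Hydrogen-Bond Corrections for Semiempirical
    Electronic Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-hoc noncovalent corrections for semiempirical
    electronic-structure energies of molecules containing elements up to
    neon. Implements a third-generation hydrogen-bond correction (donor-
    acceptor distance times five squared-cosine angular fitness factors,
    with short- and long-range sigmoidal damping) with an analytical
    Cartesian gradient assembled via internal coordinates, and a
    third-generation pairwise dispersion correction (zero damping,
    dispersion orders 6 and 8, coordination-number dependent C6
    coefficients) with an analytical two-body gradient and an optional
    triple-dipole three-body term. Includes a pluggable base-energy
    backend for composing corrected total energies, supermolecular
    interaction energies and error statistics for benchmarking against
    reference interaction energies, a cached two-parameter grid scan for
    refitting the hydrogen-bond strength parameters, programmatic
    generators for all test geometries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
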