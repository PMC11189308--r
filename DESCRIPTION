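Package: vifhelix
Title: Helical Symmetry Analysis and Lattice Modelling of Vimentin
    Intermediate Filaments
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Determines the helical architecture of intermediate filaments
    from cryo-EM style projection data and models their tetramer lattice.
    Provides averaged power spectra of filament segments, autocorrelation
    repeat measurement, zero-order-Bessel meridional scanning for the
    helical rise, layer-line picking and least-squares indexing via
    P = n * h, computational filament assembly from class averages with
    spline straightening, a domain-annotated tetramer-to-protofibril
    lattice model answering cross-section stoichiometry and geometry
    queries with PDB/MRC export, transverse cross-section extraction and
    protofibril counting with missing-wedge simulation, and a synthetic
    filament generator with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
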