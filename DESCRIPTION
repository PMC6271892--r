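Package: micellometry
Title: Small-Angle Scattering and Coordinate-Space Characterization of
    Surfactant Micelles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize micelles and other nanoscale particles
    from small-angle X-ray scattering (SAXS) and from molecular coordinate
    sets.  Implements slit-desmeared absolute-scale data reduction,
    indirect Fourier transformation (IFT) of scattering curves to the
    pair-distance distribution function p(r) in a regularized cubic
    B-spline basis, extraction of maximum dimension, radius of gyration,
    cross-section and axial ratio from p(r), Debye-equation forward
    scattering from bead models, coordinate-space descriptors (radius of
    gyration, principal extents, radial distribution functions,
    Shrake-Rupley solvent-accessible surface area, dihedral angles,
    logarithmic growth trends) and Henderson-Hasselbalch pKa fitting of
    titration curves.  Ships a seeded synthetic-data generator for bead
    ellipsoids, core-shell particles, amphiphile aggregates, solvated
    boxes and titration tables so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    minpack.lm,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
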