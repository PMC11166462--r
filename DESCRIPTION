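Package: wingmorph
Title: Dynamic Wing Shape Analysis from 3D Landmark Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for flapping wings.
    From 3D marker trajectories of a wing in flight, wingmorph segments
    stroke cycles, reconstructs the wing surface by Delaunay triangulation
    and a regularized thin-plate deformation fit, and computes per-frame
    kinematic and morphological descriptors (azimuth, elevation, wing plane
    angle, surface area, non-dimensional second moment of area, tip-to-root
    twist, chordwise and spanwise camber). Shape variation is decomposed by
    generalized Procrustes alignment, orthogonal tangent-space projection
    and singular value decomposition into ranked shape variables and
    per-frame shape scores, which are characterized by their dominant
    frequencies and in-plane/out-of-plane composition, cross-correlated
    with the descriptors, and compared between behavioural conditions with
    cyclic penalized-spline difference smooths under AR(1) residuals. A
    synthetic deforming-wing generator with known injected deformation
    modes (twist, folding, spanwise bending, area redistribution) makes
    every stage testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    signal,
    interp,
    sp,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'io.R'
    'shape-decomposition.R'
    'synthetic-wing.R'
    'temporal-stats.R'
    'wing-geometry.R'
    'wingmorph-package.R'
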