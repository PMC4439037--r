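Package: ephcompare
Title: Comparative Interface Geometry and Binding Thermodynamics of
    Eph Receptor/Ephrin Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative structural analysis of Eph
    receptor/ephrin complexes: a three-atom ephrin tilt-angle metric
    measured after least-squares (Kabsch) superposition of receptor
    ligand-binding domains, solvent-accessible surface area by the
    Shrake-Rupley method with buried interface area in the PISA
    half-sum convention, classified receptor/ligand atomic contacts
    (van der Waals, hydrogen bond, salt bridge), the Lawrence-Colman
    shape-complementarity statistic Sc, cumulative beta-strand twist,
    and simulation plus nonlinear least-squares fitting of one-set-of-
    sites isothermal titration calorimetry data.  A synthetic-fixture
    generator provides analytically solvable test cases (rotated
    two-chain complexes, sphere clusters, ideal strands, planar dot
    grids, noisy titration curves) so the whole pipeline runs without
    downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
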