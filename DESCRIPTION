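Package: cardioemx
Title: Fully Coupled Finite-Element Cardiac Electromechanics with
    Mechano-Electrical Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monolithic, fully implicit finite-element simulation of coupled
    cardiac electromechanics on hexahedral meshes. Implements three passive
    myocardial constitutive laws (a compressible and a nearly incompressible
    transversely isotropic polynomial model, and the orthotropic
    Holzapfel-Ogden exponential model), two-variable Aliev-Panfilov
    excitation with deformation-dependent conduction, an active-stress
    excitation-contraction law, and a stretch-activated mechano-electrical
    feedback current.  Ships programmatic generators for plate, cube and
    truncated-ellipsoid left-ventricle geometries with rule-based transmural
    fibers, benchmark drivers, probe analysis, and VTU/CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
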