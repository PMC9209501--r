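Package: sinusflow
Title: Vorticity Measures and Pulsatile Flow Analysis for Upper-Airway Aeration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how air moves through narrow airway passages and
    poorly ventilated side cavities such as the maxillary sinuses. Provides
    volume- and time-averaged vorticity measures (vorticity magnitude,
    helicity, absolute helicity, enstrophy, Q-criterion, lambda2) computed by
    finite differences on masked Cartesian voxel grids, nasal resistance and
    breathing-phase aggregation, a sinusoidal breathing waveform model,
    analytic velocity fields with closed-form measure values for verification,
    two-dimensional (optionally thinly extruded) airway phantoms with a narrow
    ostium and a sinus-like cavity, and a small incompressible laminar
    projection solver that drives the phantoms through a full breathing cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, Matrix, Rcpp, stats, utils, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'field-calculus.R'
    'measures.R'
    'io.R'
    'synthetic-fields.R'
    'solver.R'
    'phantom-demo.R'
    'sinusflow-package.R'
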