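Package: doseacc
Title: Offline Dose Accumulation and DVH Analysis for Fractionated
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-fraction and accumulated organ doses in
    fractionated external-beam radiotherapy without deformable registration
    or daily dose recalculation. Daily organ contours are mapped into the
    planning frame with the online rigid registration matrices recorded at
    patient setup, rasterized to voxel masks, and evaluated against the
    baseline planned dose grid. The package computes cumulative dose-volume
    histograms and ICRU-83 style metrics (D98%, D50%, D2%, mean dose, V20Gy,
    V50Gy), interfractional geometry metrics (volume deviation, centre-of-mass
    distance, Dice similarity), accumulated-course estimates with relevance
    flagging, and cohort statistics (coefficient of variation, Pearson
    correlation with Cohen strength bands). A synthetic pelvic phantom
    generator produces complete treatment courses with analytic ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry-grid.R'
    'transform.R'
    'rasterize.R'
    'mask-metrics.R'
    'dvh.R'
    'io.R'
    'phantom.R'
    'oracle.R'
    'accumulation.R'
    'course-stats.R'
    'report-io.R'
    'cli.R'
    'doseacc-package.R'
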