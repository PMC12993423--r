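# doseacc

Offline dose accumulation and DVH analysis for fractionated radiotherapy.

## The problem

In external-beam prostate radiotherapy the plan is optimized once on the
planning CT (pCT), but the anatomy changes from session to session: the
bladder fills and empties, the rectum varies, the prostate shifts by a few
millimetres. Daily cone-beam CTs and automatic contouring make the daily
anatomy available, and the rigid couch-correction transform recorded at
patient setup links each daily image to the planning frame. `doseacc`
estimates the dose each organ actually accumulates over the course **without
deformable registration and without recalculating dose**: daily contours are
mapped into the planning frame with the online registration matrix,
rasterized to voxel masks, and evaluated against the baseline planned dose
grid.

For every fraction and for the accumulated course the package reports:

- **ICRU-83 style dose-volume metrics** — D98%, D50%, D2%, mean dose, V20Gy,
  V50Gy, where D_x% is the (100−x)th percentile of the structure's dose
  distribution and V_xGy the percent of volume receiving at least x Gy;
- **geometric change metrics** — relative volume deviation vs the pCT,
  centre-of-mass distance (CMD), and the Dice similarity coefficient
  DSC = 2|A∩B| / (|A| + |B|);
- **deviations vs the planned baseline**, flagged when they exceed a
  relevance threshold (default 2%);
- **cohort statistics** — interfractional coefficient of variation
  CV = σ/μ × 100% of volume series, and Pearson correlations between volume
  change and mean-dose change with Cohen strength bands.

The accumulated cumulative DVH per structure is the equal-weight mean of the
daily cumulative (relative-volume) curves in plan-total Gy: with each
fraction delivering 1/n of the plan and sub-volumes treated as exchangeable
across fractions, this mean is the accumulated-dose estimate.

Because clinical DICOM-RT exports cannot ship with the package, courses are
exchanged as plain-text equivalents (JSON dose grid with integer values plus
scaling factor, JSON structure sets, 4-line text registration matrices, a
YAML manifest), and a **synthetic pelvic phantom generator** produces
complete, loadable treatment courses with analytic ground truth: a 60 Gy /
20-fraction plan, lognormal organ-volume variation calibrated to per-organ
CV targets (bladder 35.2%, rectum 20.6%, prostate 9.5%), Gaussian prostate
displacement (mean 3.35 mm), and rigid setup errors recorded inversely in
the emitted registration matrices.

## Worked example

```r
library(doseacc)

cfg    <- phantomConfig(seed = 1, nFractions = 5)  # down-scaled course
sim    <- simulateCourse(cfg)
report <- runCourse(sim$course)
report
#> CourseReport: 5 fraction(s) evaluated (0 failed), structures: body, bladder, rectum, prostate, prostate+1cm
#>   accumulated metrics beyond 2% threshold: 10

round(report@baseline@metrics$prostate, 2)
#>    D98_Gy    D50_Gy     D2_Gy  Dmean_Gy V20Gy_pct V50Gy_pct
#>     59.56     59.83     59.98     59.82    100.00    100.00

round(report@accumulated@deviationPct$bladder, 2)
#>    D98_Gy    D50_Gy     D2_Gy  Dmean_Gy V20Gy_pct V50Gy_pct
#>     35.59    109.06     -0.45     14.51     15.16      3.40

thresholdExceedanceRate(report@fractionResults, "Dmean_Gy", "bladder", 2)
#> [1] 80

volumeDoseCorrelation(report, "bladder")
#> Pearson r = -1.000 (n = 5): strong negative correlation

round(report@stats$prostate_cmd$mean, 2)
#> [1] 3.88
```

Reading: the planning prostate sits on the 60 Gy plateau (baseline mean dose
59.8 Gy, D98 59.6 Gy). Over five simulated sessions the bladder's
accumulated mean dose deviates +14.5% from plan and its near-minimum and
median doses far more — low-dose bladder metrics are tiny numbers, so small
absolute shifts give large percentages — and 80% of sessions exceed the 2%
threshold on bladder mean dose. Bladder volume change and mean-dose change
correlate negatively: an inflating bladder carries most of its volume away
from the high-dose region. The prostate's mean daily centre-of-mass distance
to planning is 3.9 mm.

`writeCourseReport(report, "out/")` serializes the report (JSON, per-fraction
CSV, DVH curves); `generateCourse(cfg, "course/")` writes a loadable course
to disk, and `loadCourse("course/course.yaml")` reads one. The same workflow
is scriptable via `inst/scripts/doseacc` (`simulate`, `accumulate`,
`cohort`).

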