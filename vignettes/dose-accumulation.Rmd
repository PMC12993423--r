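---
title: "Methods: offline dose accumulation from daily contours and rigid registrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: offline dose accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(doseacc)
```

# The estimation problem

A fractionated radiotherapy course delivers a planned dose distribution
$D(\mathbf{x})$, optimized on the planning CT, in $n$ daily sessions. The
anatomy at each session differs from planning: organ volumes change, the
prostate shifts, and the patient is repositioned by a rigid couch correction
recorded as a $4 \times 4$ homogeneous matrix. `doseacc` estimates session
and accumulated organ doses under two assumptions that define the offline
(non-adaptive) monitoring setting:

1. **The delivered dose field is the planned one.** No daily dose
   recalculation is performed; each session is assumed to deliver $D/n$ in
   the planning frame. This is justified when tissue density changes are
   small relative to the geometric changes being monitored (soft-tissue
   organs near the target have near-water density).
2. **Rigid anatomy transfer.** Daily contours are mapped into the planning
   frame by the online registration matrix alone; residual deformation is
   not modelled (no deformable image registration).

Under these assumptions the only new information each day is geometric, and
the per-session evaluation is: transform the daily contours with the
registration matrix, rasterize them on a common grid, and read the planned
dose inside them.

# Per-session evaluation

**Contour transform.** Vertices are mapped through the homogeneous matrix
(or its inverse, selected by the course's `matrix_maps` convention, since
vendors disagree on whether the stored matrix maps daily-to-planning or the
reverse). A pure translation — the typical online correction — keeps contours
planar and is applied exactly. A rotational component tilts the contour
planes; each contour is then re-binned onto the plane at its mean
transformed $z$. The projection error is bounded by the contour's in-plane
radius times the sine of the tilt, sub-voxel for couch rotations of a few
degrees; we chose this vertex-level re-binning over mask-resampling because
it preserves polygon topology and the exactness of the translation path.

**Rasterization.** Masks live on the plan dose grid resampled to isotropic
1 mm (configurable, `geometrySpacingMm`). A voxel is set when the majority
of a supersampled in-plane point grid (default $2 \times 2$ per voxel) falls
inside an odd number of polygons — the even–odd rule, so nested contours make
holes — with exact ties resolved by the voxel-centre parity, which keeps
boundary coverage unbiased (a one-sided tie rule biases volumes by about 1%
at clinical organ sizes). Along $z$, each grid slice takes the nearest
contour plane within half the contour-plane spacing: when contours are
coarser than the grid (3 mm CT slices on a 1 mm grid) this extrudes each
contour over its slab, the standard reconstruction for axial stacks; when
spacings match it reduces to nearest-slice assignment.

**Dose sampling and DVH.** The plan dose is interpolated trilinearly at the
set-voxel centres (dose grids are coarser than the geometry grid;
nearest-neighbour sampling is retained only as an oracle mode). Voxels
outside the dose grid are excluded and counted, tolerated up to 5% of the
structure (configurable) to accommodate truncated daily fields of view, and
fatal beyond that. Metrics are computed from the raw samples — percentiles by
linear interpolation between order statistics, $V_{x\,\mathrm{Gy}}$ by direct
counting — so they carry no binning bias; cumulative curves (0.1 Gy bins by
default, the bin width is a reporting choice, not part of the estimator) are
kept for plotting and accumulation.

**Geometry metrics.** Volume deviation, centre-of-mass distance (CMD) and
Dice coefficient are computed between the transformed daily mask and the
planning mask on the same grid — i.e. they measure the *residual after setup
correction*, which is the quantity relevant to dose. The centre of mass is
the unweighted mean of set-voxel centres (contours carry no density). The
target surrogate "prostate + 1 cm" is built by a Euclidean distance
transform (anisotropic-spacing aware) and regenerated from the *daily*
prostate each session, mirroring a pipeline that derives the target
automatically rather than transforming the planning target.

# Accumulation

No closed-form accumulated dose exists without voxel correspondence across
sessions. We adopt the exchangeable-volume estimate: each fraction delivers
$1/n$ of the plan, and the accumulated cumulative DVH of a structure is the
equal-weight mean of the daily cumulative relative-volume curves on a common
plan-total dose axis. For partial courses the mean runs over the available
fractions (recorded as `nAvailable`). Two properties anchor this choice: an
identity course (daily anatomy equal to planning, identity registrations)
reproduces the baseline curve exactly, and for uniform per-session organ
doses the estimate reduces to the arithmetic mean dose.

Accumulated *metrics* are read off the accumulated curve (D_x% from the dose
where the curve crosses x, mean dose by trapezoidal integration). Their
deviations against baseline are computed against baseline metrics derived
from the baseline *curve* with the same estimator — comparing like with
like — so the identity course yields exactly zero deviation even for metrics
that sit in low-dose tails where a half-bin estimator difference would
otherwise masquerade as a percent-level deviation. The raw-sample baseline
metrics remain the reported baseline values. Deviations are percentages of
the planned value, flagged when $|\Delta| >$ 2% (the conventional relevance
threshold, configurable); a zero baseline metric yields a missing deviation
rather than a division blow-up.

# Cohort statistics

Interfractional variability is summarized by the coefficient of variation
$\mathrm{CV} = \sigma/\mu \times 100\%$ of a structure's volume series, with
the sample ($n-1$) standard deviation — the population/sample choice is not
standardized in the field; sample SD is the conservative choice for short
courses. Volume–dose coupling is assessed by the Pearson correlation between
daily relative volume change and daily mean-dose deviation, pooled across
fractions (and courses), with Cohen banding: $|r| < 0.3$ weak, $> 0.5$
strong, the boundary values moderate (the literal reading of the printed
inequalities). Pooling ignores within-patient clustering; the pooled $n$ is
recorded so readers can judge the effective sample size. Distribution
summaries always carry mean, SD, median and quartiles (linear interpolation
between order statistics); the automatic presentation switches to
median/IQR when $|$skewness$| > 1$.

# The synthetic phantom

The generator stands in for the clinical chain (planning export, daily
cone-beam imaging, AI contouring) and provides analytic ground truth.

*Anatomy.* Body as an elliptic cylinder; bladder as a sphere
(radius 36.63 mm, 205.9 cm³), rectum as a cylinder (r 15 mm, length 104 mm,
73.5 cm³), prostate as an ellipsoid (semi-axes 25, 22, 18.3 mm, 42.2 cm³) —
typical cohort-mean volumes for this treatment site. Contours are emitted as
64-vertex polygons at the CT slice positions (1, 1, 3 mm grid).

*Dose.* A logistic plateau over the prostate + 1 cm margin in an ellipsoidal
radial coordinate: 50% dose 15 mm beyond the margin surface
(`plateauShoulderMm`), falloff scale 5 mm (`falloffMm`), prescription 60 Gy
in 20 fractions. The shoulder is chosen so the entire baseline prostate sits
above 98% of prescription (a generator invariant, checked at configuration
time); the smooth falloff makes organ dose differentiable in position, so
displacement and volume effects are well-defined.

*Interfractional variation.* Organ volumes are scaled by lognormal factors
with $\sigma^2 = \log(1 + \mathrm{CV}^2)$ and unit mean, calibrated to the
per-organ CV targets (defaults 35.2% bladder, 20.6% rectum, 9.5% prostate,
2% body); scaling is isotropic about the organ centre, and the bladder
additionally drifts superiorly with filling (10 mm per unit volume-factor
excess), the mechanism that produces the negative volume–dose correlation.
The prostate centre is displaced by a per-axis Gaussian (SD 2.10 mm, giving
mean 3-D displacement $2.10\sqrt{8/\pi} = 3.35$ mm). A rigid setup error
(per-axis SD 3 mm) shifts all daily structures and is recorded inversely in
the emitted registration matrix, so applying the matrix restores everything
except the true anatomical change. Every draw is a deterministic function of
the seed and the fraction index.

*What the phantom does not emulate:* contouring error and observer
variability, deformation (organs change size but not shape class), imaging
artifacts and truncated fields of view (except as an error-path test), and
density changes — so passing tests demonstrate the correctness of the
geometric/dosimetric machinery under the stated assumptions, not robustness
to contouring noise on real images.

*Oracle.* For validation, metrics are recomputed rasterization-free by
sampling the dose at quasi-random points (seeded Latin-hypercube strata,
rejection-sampled with the analytic inside test) inside the true shapes —
including the margin target, whose inside test solves the ellipsoid
closest-point equation by vectorized Newton iteration. Agreement of the
pipeline with this oracle within 1% of prescription validates the whole
rasterize–sample–accumulate chain.

# Numerical choices and degenerate inputs

- Dose files store integers times a scaling factor (default 1 mGy quantum),
  so write–read round trips are exact to one quantum; contour vertices are
  written with six significant digits (round trip within $10^{-3}$ mm).
- Slice offsets must be uniform within $10^{-3}$ mm; non-axial orientations
  are rejected (the pipeline operates on axial stacks).
- Rigidity of registrations is enforced to $10^{-4}$ on $R^TR - I$.
- Dice of two empty masks is an error (a pipeline fault), one empty mask
  gives 0 (true disagreement); empty structures raise rather than returning
  zeros; a zero baseline volume yields a missing volume deviation.
- Percentile boundary ties and plateaus in curve inversion take the
  rightmost crossing, making D50 of a half-and-half dose distribution the
  upper level (the minimum dose to the hottest half).

# Problem sizes

The shipped tests and the acceptance script run the default-size phantom
(about 0.6 M dose voxels, 4–5 M geometry voxels) for 20-fraction courses,
200 fractions for parameter recovery, and $10^5$ oracle points per organ per
fraction; a down-scaled phantom (about 8× fewer voxels) backs the fast unit
tests. These sizes were chosen to exercise clinically realistic grids while
keeping a full validation run in the minutes range on one CPU.

# Known limitations

- Accumulation assumes volume-fraction exchangeability across sessions; it
  estimates the accumulated *distribution* of dose over the organ, not
  voxel-wise accumulated dose, and cannot capture systematic sub-volume
  effects that deformable registration would reveal.
- Session doses reuse the planned field; large body-contour changes (which
  alter attenuation) violate this, and the body-volume CV is the intended
  screening quantity for such cases.
- Rotational registrations are supported with sub-voxel approximation only
  for small angles; large rotations would need true mask resampling.
- No biological weighting (EQD2/NTCP) is applied; metrics are physical dose.
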