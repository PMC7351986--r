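---
title: "Quantifying the medial-lateral geography of deep cervical extensor fat infiltration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the medial-lateral geography of deep cervical extensor fat infiltration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfigeo)
```

## The scientific question

Muscle fat infiltration (MFI) in the deep cervical extensors (multifidus
and semispinalis cervicis) is not uniform across the muscle
cross-section: fat concentrates medially, near the spinous process.
After whiplash trauma, people who recover poorly appear to carry *more*
fat specifically in that medial zone, while the lateral muscle looks
similar across recovery outcomes. `mfigeo` implements the measurement
and inference pipeline needed to test that geography: fat-fraction
mapping from fat/water-separated (2-point Dixon) MRI, medial-to-lateral
quartile partitioning of each muscle cross-section, aggregation to one
MFI value per participant, cervical level (C4-C7) and quartile, and a
per-level repeated-measures linear mixed model comparing recovery
groups within quartiles.

Recovery groups are defined from the Neck Disability Index (NDI, a
0-100% self-report disability score) at 12 months post collision:
severe (NDI >= 30), mild (10 <= NDI < 30), recovered (NDI < 10). We
read "10-29%" as the half-open interval [10, 30) so the three bands
tile [0, 100] even for non-integer scores.

## The measurement model

**Fat fraction.** At each voxel, MFI = $100 \cdot I_F / (I_F + I_W)$,
where $I_F$ and $I_W$ are the fat- and water-image intensities. The
ratio is invariant to any common rescaling of the two channels, so no
intensity normalisation or bias-field correction is applied. A voxel
with $I_F + I_W = 0$ carries no measurement: it is flagged invalid and
excluded from every downstream mean, rather than being scored 0 or 100.

**Quartile geometry.** Each slice-side ROI is ranked by the unsigned
column distance of its voxels from a per-slice spinous-process landmark
column (the medial-lateral coordinate; ties broken by row then column
index, all indices 1-based), then cut into four contiguous rank bins:
Q1 most medial through Q4 most lateral. The default rule is
*equal-area* (bin sizes differ by at most one voxel, larger bins placed
medially first), which makes the four per-quartile means equally
precise; an *equal-width* rule (bin edges at quarters of the coordinate
range) is available via `rule = "width"` because the original
delineation rule is not recoverable and plausible custom scripts could
implement either. The medial-lateral axis is the image-column distance
from the landmark, not the ROI's principal axis: it is simple,
auditable, and matches the anatomical description of Q1 abutting the
spinous process.

**Aggregation.** For each level the three slices centred on the
midpoint of the level's annotated slice range are used
(`floor((first + last)/2)` and its neighbours) — central slices are
least affected by ambiguity about where one vertebral level ends.
Within a level x quartile cell, all valid voxels of the three slices
and both sides are pooled before averaging (voxel-weighted), so each
side contributes in proportion to its measured tissue; averaging the
two side means instead is available via `bilateral = "side-mean"`.
Cells with no valid voxels propagate as missing to the model — mixed
models tolerate unbalanced data — and are never imputed.

## The inference model

Each cervical level gets its own linear mixed model of the
participant x quartile MFI values:

$$\text{MFI}_{ij} = \beta_0 + \boldsymbol\beta_g \text{group}_i +
\boldsymbol\beta_q \text{quartile}_j + \boldsymbol\beta_{gq}
(\text{group} \times \text{quartile})_{ij} + \beta_a \text{age}_i +
\beta_s \text{sex}_i + \beta_b \text{BMI}_i + u_{0i} + u_{1i} j +
\varepsilon_{ij}$$

- Quartile enters the fixed part as a 4-level factor (the
  medial-lateral profile is non-linear), with Q4 as reference; group
  has `recovered` as reference.
- $(u_{0i}, u_{1i})$ are a per-participant random intercept and random
  slope on the numeric quartile index 1-4 with unstructured 2x2
  covariance: participants differ both in overall MFI and in how
  steeply MFI changes across quartiles. A full categorical random
  quartile effect would be over-parameterized at n near 61.
- Age and BMI are centred at their sample means before fitting so the
  estimated marginal means sit at covariate means; this changes no
  test.
- Estimation is REML (`lme4`); tests and degrees of freedom use the
  Satterthwaite approximation (`lmerTest`), and the method name is
  recorded in the model spec. The original analysis tool's covariance
  structure and df method are not printed anywhere recoverable, so
  these are documented defaults, not claims.
- Pairwise intra-quartile group contrasts (severe-recovered,
  mild-recovered, severe-mild) are estimated-marginal-mean differences
  (`emmeans`) at covariate means, unadjusted by default (matching
  plain per-comparison p < 0.05 reporting); Bonferroni within each
  quartile's family of three is a flag away. Alpha defaults to 0.05.

```{r example, eval = FALSE}
co  <- simulate_cohort(10, 26, 25, seed = 1)   # synthetic Dixon cohort
tab <- cohort_analysis_table(co)               # participant x level x quartile
res <- run_all_levels(tab)                     # four mixed models
subset(res$contrasts, quartile == 1)
```

## What the synthetic generator emulates — and what it does not

The generator produces, per participant, paired fat/water volumes, a
shared labelled mask (one elliptical ROI per side per slice, 3 slices
per level, landmark at the grid's middle column), metadata, and the
exact ground truth. Target MFI at a voxel in quartile $q$ is the group
x level profile mean plus a participant random intercept
($\sigma_0 = 4$ MFI% by default) plus a participant random slope times
$q$ ($\sigma_1 = 1$ MFI% per quartile step), clipped to [0, 100].
Intensities invert the fat-fraction relation around a reference total
signal (1000 units) with additive zero-mean Gaussian voxel noise
(SD 50 units), truncated so intensities stay non-negative; a Rician
noise model was deliberately not used — at the default signal-to-noise
level the Gaussian approximation is standard and the noise model is a
config switch, not a finding.

Default profile means put the recovered group at (28, 18, 15, 14.5)
MFI% for Q1-Q4, with Q1 raised to 36 (mild) and 40 (severe) at all
levels and Q2 raised to 22/24 at C4-C5 only. These numbers are this
package's calibration, chosen so that the qualitative geography —
Q1 highest everywhere; symptomatic elevation in Q1 at all levels and
Q2 only at C4-C5; no lateral group differences — emerges reliably at
group sizes 10/26/25. No per-quartile numeric MFI values are published
for the study cohort, so true effect sizes are unknown and live in
config, never asserted as fact. Demographic defaults (age, BMI, sex
mix per group) follow the reported cohort descriptives; NDI is drawn
uniformly within each group's band, the least-assumptive
band-respecting choice.

What passing tests on this generator do **not** show: robustness to
real cervical anatomy (muscle shape varies per person and per slice;
here the mask is shared), pulse-sequence physics, motion or aliasing
artifacts, segmentation error, or Rician noise floors at low SNR.
They do show that the geometry, aggregation and inference machinery
are correct on data whose truth is known exactly.

## Numerical and design notes

- **Zero-signal voxels** are invalid/missing, never 0: no signal means
  no measurement (whether the original workflow excluded or zero-filled
  such voxels is unstated; exclusion is the defensible choice).
- **Quartile ties** are broken by row-major rank, and remainder voxels
  go to the more medial bins — both fixed conventions so counts are
  bit-reproducible.
- **Degenerate ROIs**: a single-voxel ROI is all Q1; empty required
  slice-sides are recorded as missing and skipped, not fatal.
- **Determinism**: every source of randomness derives from one
  top-level seed, fanned out per participant, so a participant's
  volume depends only on (seed, participant index) and regeneration is
  order-independent. Reruns with identical config and seed reproduce
  all numeric outputs.
- **Degenerate random-effects limit**: when the true random-effect
  variances are zero, the REML estimates land exactly on the zero
  boundary for a sizeable fraction of datasets, and for those fits the
  fixed effects coincide with OLS to numerical precision; on the
  remaining datasets the within-participant coefficients (quartile and
  group x quartile) still match OLS exactly by the balanced-design
  invariance. The test suite checks both facets rather than pretending
  every fit sits on the boundary.
- **Simulation sizes**: operating-characteristic runs use a 48 x 80
  grid with 14 x 6-voxel ellipse semi-axes (about 390 pooled voxels
  per cell), 200 null replicates at n = 10/10/10 for type-I error and
  100 replicates at n = 10/26/25 for power — sizes at which the
  Monte-Carlo error of a 5% rejection rate is about 1.5-2 percentage
  points and a laptop core finishes in minutes.

## Known limitations

Only the 12-month time point is modelled; earlier post-injury time
points, longitudinal trajectories, muscle cross-sectional area or
volume outcomes, and automatic landmark detection are out of scope.
The left/right label convention is image-based (lower/higher column
index), not radiological. Group assignment at the 29-30 NDI boundary
follows this package's half-open convention; scores in (29, 30) are
classified mild.
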