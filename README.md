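# mfigeo

Where does fat sit inside the deep neck extensor muscles, and does that
geography differ between people who recover from whiplash and people
who do not? `mfigeo` is an R package for quantifying the
medial-to-lateral distribution of muscle fat infiltration (MFI) in the
deep cervical extensors (multifidus + semispinalis cervicis) from
fat/water-separated (2-point Dixon) MRI, and for comparing that
distribution between recovery groups defined by the Neck Disability
Index (NDI).

It is aimed at musculoskeletal imaging researchers who have (or want to
simulate) paired fat/water volumes with muscle segmentations, and who
want the whole path from voxels to per-level group inference in one
tested pipeline.

## What it computes

1. **Fat-fraction maps** — per voxel, MFI = 100·I_F/(I_F + I_W);
   zero-signal voxels are flagged invalid, never scored 0 or 100.
2. **Medial-lateral quartiles** — each slice-side ROI is ranked by
   column distance from a per-slice spinous-process landmark and cut
   into four equal-area bins, Q1 (most medial, abutting the spinous
   process) to Q4 (most lateral).
3. **The analysis table** — MFI per participant × cervical level
   (C4-C7) × quartile, pooling valid voxels of the level's three
   central slices and both sides.
4. **Recovery groups and participant flow** — NDI ≥ 30 severe,
   10-29 mild, < 10 recovered; plus enrolment/attrition/exclusion
   accounting.
5. **Per-level mixed models** — for each level,
   `MFI ~ group * quartile + age + sex + BMI` with a per-participant
   random intercept and random slope on the quartile index (REML,
   Satterthwaite df), followed by pairwise estimated-marginal-mean
   group contrasts within each quartile.

A synthetic Dixon-cohort generator produces volumes, masks, metadata
and exact ground truth, so the full pipeline is testable end-to-end
without any imaging data, and `power_typeI_study()` measures the
pipeline's operating characteristics (type-I error, power) by
simulation.

## Worked example

```r
library(mfigeo)

co  <- simulate_cohort(10, 26, 25, seed = 1)  # 61 synthetic participants
tab <- cohort_analysis_table(co)              # 976 rows: 61 x 4 levels x 4 quartiles
res <- run_all_levels(tab)
res
#> Per-level mixed models (4 level(s)); alpha = 0.05, adjust = none
#>   C4 Q1: mild-recovered
#>   C4 Q1: severe-mild
#>   C4 Q1: severe-recovered
#>   C5 Q1: mild-recovered
#>   C5 Q1: severe-mild
#>   C5 Q1: severe-recovered
#>   C6 Q1: mild-recovered
#>   C6 Q1: severe-recovered
#>   C7 Q1: mild-recovered
#>   C7 Q1: severe-mild
#>   C7 Q1: severe-recovered

head(subset(res$contrasts, quartile == 1 & level == "C4"), 3)
#>   level quartile         contrast estimate       se       df        t            p significant
#> 1    C4        1   mild-recovered 6.016549 1.404476 55.07506 4.283840 7.425894e-05        TRUE
#> 2    C4        1      severe-mild 3.408043 1.604315 55.08454 2.124298 3.814869e-02        TRUE
#> 3    C4        1 severe-recovered 9.424592 1.883776 55.07474 5.003031 6.111355e-06        TRUE
```

Reading the output: on this simulated cohort the symptomatic groups
carry significantly more MFI than the recovered group in the most
medial quartile (Q1) at every level — e.g. at C4 the severe group sits
about 9.4 MFI percentage points above the recovered group at covariate
means — while the lateral quartiles (Q3, Q4) show no significant group
differences anywhere. That is the medial-concentration pattern the
generator is calibrated to emulate (Q2 elevation at C4-C5 is present in
the generating truth too, and reaches significance in most but not all
single cohorts).

Run from the shell instead:

```sh
Rscript inst/cli/mfigeo.R run-all --out out/ --seed 1
Rscript inst/cli/mfigeo.R flow-report --enrolled 97 --attrition 19 \
    --poor-quality 1 --not-amenable 16 --out flow.json
```

## Documentation

The methods vignette (`vignettes/mfi-geography.Rmd`) documents the
measurement model, the mixed-model specification and its defaults, what
the synthetic generator does and does not emulate, and the package's
numerical conventions.
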