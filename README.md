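# IVCMgrade

Multimodal dry-eye analysis in R: morphometry of corneal in vivo confocal
microscopy (IVCM) frames, an ordinal IVCM grading score, bead-calibrated
conjunctival HLA-DR quantification, and the nonparametric statistics that
tie them together — plus calibrated synthetic cohorts and synthetic IVCM
frames with exact ground truth, so the whole pipeline is testable without
patient data.

## Who this is for

Researchers analysing dry eye disease (DED) with IVCM of the sub-basal
nerve plexus alongside clinical testing (OSDI, Schirmer, tear break-up
time, Oxford staining) and flow-cytometric HLA-DR quantification, and
anyone who needs a reproducible reference implementation of this kind of
grading-and-correlation analysis.

## The score at the core

Each eye is graded from per-eye averages over its five sharpest frames
(400 × 400 µm, 384 × 384 px, 0.16 mm² per frame):

| Subscore | Input | Grades |
|---|---|---|
| ICsc (0–3) | inflammatory-cell density (cells/mm²) | `[0,10)` IC-0, `[10,50)` IC-1, `[50,100)` IC-2, `[100,∞)` IC-3 |
| NDsc (0–1) | nerve fiber density (nerves/mm²) | > 15 normal (ND-1), ≤ 15 decreased (ND-2) |
| NMsc (0–2) | reflectivity / tortuosity flags | NM-0, NM1-R, NM1-T, NM-2 |

The total score T-IVCM = ICsc + NDsc + NMsc ranges 0–6. Nerve metrics
follow the standard definitions: NFD is polylines per mm², NFL is summed
traced length in mm per mm², tortuosity is the arc/chord ratio. HLA-DR
mean fluorescence intensities convert to arbitrary units of fluorescence
through a log10–log10 least-squares bead calibration
(`AUF = 10^(a + b·log10(MFI − background))`). Associations are assessed
with tie-corrected Spearman correlations (exact permutation p-values at
small n) and Mann-Whitney tests (exact enumeration at small n), masked at
α = 0.05.

The cohort simulator is a Gaussian copula whose marginals are
moment-matched to published per-group summaries (214 eyes: 63 autoimmune
/ 151 non-autoimmune) and whose latent correlations are calibrated by
bisection so the *binned* scores reach their Spearman targets — in
particular Spearman ≈ 0.30 between both ICsc and T-IVCM and HLA-DR. See
the methods vignette (`vignettes/ivcm-grading-methods.Rmd`) for the full
model and its assumptions.

## Worked example

```r
library(IVCMgrade)

## grade one eye's morphometry summary
ivcmScore(list(mean_ic_density = 75, mean_nfd = 12,
               mean_tortuosity = 1.35, mean_reflectivity = 1.8))
#> IVCMScore: total 4 (IC-2 + ND-2 + NM1-T)
```

75 cells/mm² is medium-high density (IC-2, 2 points), 12 nerves/mm² is
decreased (ND-2, 1 point), and the tortuosity index 1.35 exceeds the 1.2
flag threshold while reflectivity 1.8 does not (NM1-T, 1 point): total 4.

```r
## a calibrated synthetic cohort matching the published summary table
cfg    <- calibrateCohortConfig(table1Default(), seed = 1)
cohort <- generateCohort(cfg, seed = 1)
table(cohort$group)
#>  AIDED NAIDED
#>     63    151

## high- vs low-inflammation eyes differ in conjunctival HLA-DR
compareHlaByIcsc(cohort)
#> GroupComparison (normal approximation): high ICsc (n=35) vs low ICsc (n=179)
#>   U = 4097, p = 0.004011; means 9.013e+04 vs 7.061e+04

## significance-masked Spearman correlogram
cr <- spearmanMatrix(cohort, c("age", "schirmer_mm", "tbut_s",
                               "ic_sub", "tivcm", "hla_dr_auf"))
significantEdges(cr)
#>          var1       var2       rho            p sign
#> 1 schirmer_mm     tbut_s 0.4362879 2.343811e-11    +
#> 2         age      tivcm 0.2501994 2.176047e-04    +
#> 3      ic_sub      tivcm 0.6726770 1.503907e-29    +
#> 4      ic_sub hla_dr_auf 0.3305948 7.510240e-07    +
#> 5       tivcm hla_dr_auf 0.4048025 7.629686e-10    +
```

In this cohort (seed 1) the total score and its inflammatory-cell
subscore correlate with HLA-DR, the tear-film tests correlate with each
other, and age tracks the total score — the structure the generator
plants. Per-cohort correlations fluctuate around the calibrated 0.30
target (here 0.40 at n = 214); averaged over 20 replicate cohorts they
sit within ±0.05 of it.

```r
## bead calibration: collinear beads recover the line exactly
cal <- fitBeadCalibration(data.frame(mfi = c(100, 1000, 10000),
                                     abc = c(1e3, 1e4, 1e5)))
cal
#> BeadCalibration: log10(AUF) = 1.0000 + 1.0000 log10(MFI), R^2 = 1.0000 (3 beads)
mfiToAuf(cal, 500)
#> [1] 5000

## everything end to end, with a reproducibility manifest
runPipeline(cfg, seed = 1, outDir = "ivcm-run")
```

`runPipeline()` writes the cohort table, rendered frames with annotation
TSVs, per-frame and per-eye morphometry, scores, the bead calibration
round trip, correlogram matrices and stratification summaries, plus a
`manifest.json` whose hash is identical across reruns with the same
configuration and seed. A thin command-line wrapper lives at
`inst/scripts/ivcm-pipeline.R`.

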