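---
title: "Methods: corneal confocal grading, synthetic cohorts and HLA-DR calibration"
author: "IVCMgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corneal confocal grading, synthetic cohorts and HLA-DR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IVCMgrade)
```

# The problem

Dry eye disease (DED) lacks a single gold-standard sign, so multimodal
evaluation combines symptom questionnaires (OSDI), tear-film tests
(Schirmer, tear break-up time), surface staining (Oxford score), cellular
imaging of the cornea by in vivo confocal microscopy (IVCM), and molecular
markers of ocular-surface inflammation such as conjunctival HLA-DR
expression measured by flow cytometry. IVCMgrade implements the analysis
layer of such a study: per-frame and per-eye morphometry of the sub-basal
nerve plexus, an ordinal grading score built from that morphometry, the
bead calibration that converts fluorescence intensities to comparable
units, and the nonparametric statistics that relate all of these. Because
patient images and tables from such studies are rarely deposited, the
package also ships two synthetic-data generators — a cohort simulator and
an IVCM frame renderer — that are first-class, tested components: they
define the conditions under which every downstream claim is verified.

# The grading score

Each eye receives three subscores from its averaged morphometry:

* **ICsc (0–3)** — mean inflammatory-cell (dendritic-cell) density
  in cells/mm²: `[0,10)` → 0 (IC-0), `[10,50)` → 1 (IC-1), `[50,100)` → 2
  (IC-2), `[100,∞)` → 3 (IC-3).
* **NDsc (0–1)** — mean nerve fiber density: more than 15 nerves/mm² is
  normal (ND-1, 0); 15 or fewer is decreased (ND-2, 1). The boundary
  value is decreased.
* **NMsc (0–2)** — one point each for abnormal reflectivity (NM1-R) and
  abnormal tortuosity (NM1-T); both give NM-2, neither NM-0.

The total score is the sum, 0–6. The published category limits leave the
half-open intervals (49, 50) and (99, 100) unassigned and write the top
category as "> 100"; since densities are real-valued averages of five
frames, we read the printed integers as bin edges and use half-open bins,
so 100 cells/mm² grades IC-3 and every non-negative density is scored.
This is a deliberate, documented deviation from the literal table text.

Reflectivity and tortuosity grading is qualitative in clinical practice.
The package operationalises the two flags as thresholds on per-eye means —
tortuosity index above 1.2 and reflectivity index above 2.5 by default —
configurable in every entry point and stored in the cohort configuration,
never hard-coded at call sites. The tortuosity index is the arc-length to
chord-length ratio of a traced nerve (1 = straight), the simplest
published index consistent with a binary grading input; the reflectivity
index is mean intensity along the nerve divided by the robust (median)
background farther than 5 px from any nerve.

Per patient, a single eye enters the analysis: the one with the worse
Oxford staining score, then the more painful one, then a seeded random
choice on a full tie (`selectWorstEye()`).

# Morphometry

The confocal frame covers 400 × 400 µm digitised to 384 × 384 px, so the
pixel size is exactly 400/384 µm and the field is 0.16 mm². All densities
are per mm²: cell density is count/0.16; nerve fiber density (NFD) counts
annotated polylines per mm² (each annotated trunk or branch is one
polyline — the package counts polylines and documents it, since no
branch-merging rule is published); nerve fiber length (NFL, mm/mm²) is
the summed polyline arc length converted to mm and divided by 0.16.
Per-eye summaries average the five sharpest frames; sharpness is the
variance of the 3 × 3 Laplacian response, the standard objective proxy
for "quality of contrast and focus", with ties broken by input order.
Whether nerve density should be computed per frame and averaged or on a
mosaic is not documented in the source study; the package averages
per-frame values.

The canonical pipeline consumes annotation files (mirroring manual
counting); `detectCells()` is an optional automated path — a
Laplacian-of-Gaussian blob detector at the cell scale (σ = 3 px ≈ 3 µm)
with a Hessian shape test that rejects elongated (nerve-ridge) maxima.
On noiseless rendered frames it recovers planted counts exactly, and it
keeps recall above 0.9 at the default noise level; real HRT-II frames
carry texture the renderer does not model, so those figures bound the
detector's behaviour on clean geometry only.

# The synthetic cohort generator

The generator is a Gaussian copula over 14 latent variables per eye: the
clinical variables, the four latent morphometric traits (cell density,
nerve density, tortuosity, reflectivity) and HLA-DR. The defaults
(`table1Default()`) encode the published cohort: 214 eyes of 214 patients,
63 with autoimmune (AIDED) and 151 with non-autoimmune (NAIDED) DED,
per-group means and SDs for every clinical variable, and female fractions
of 97%/68%.

**Marginals.** Clinical variables use truncated normals whose underlying
parameters are moment-matched so the *truncated* distribution has the
printed mean and SD (truncation near a bound, e.g. Schirmer 9.7 ± 9.8 mm
at 0, would otherwise bias the mean by several mm). Oxford (0–5) and pain
(0–10) are rounded to their integer grids, with the moment matching done
on the rounded distribution. HLA-DR uses a moment-matched lognormal
(mean 72,000/70,000, SD 62,000/66,000 arbitrary units per group — the
heavy right tail is forced by an SD comparable to the mean). OSDI
subscales are generated directly on the printed scales without
reconciling them against the standard OSDI formula, since the source
scales are not documented; the totals are truncated to [0, 100]. The
pain marginal (4 ± 2.5, not published) is a free parameter that only
feeds the worst-eye tie-break.

**Morphometric traits** use lognormal families whose parameters are
pinned by the only moment information available — the printed *subscore*
summaries. The cell-density lognormal is moment-matched so its
Table-binned ICsc has mean 1.7 and SD 0.6/0.7; the nerve-density
lognormal (spread fixed at sdlog 0.5) is pinned by P(NFD ≤ 15) = 0.4,
the NDsc mean; tortuosity (1 + lognormal) and reflectivity (lognormal)
are pinned by the two flag probabilities solved from the NMsc mean and SD
under independent flags (the larger probability is assigned to
reflectivity, the commoner abnormality in DED). Scores are then *induced*
by grading each simulated eye through the scoring module — never pasted —
so every scored cohort automatically satisfies the scoring invariants.

**Correlations.** Monotone marginal transforms preserve Spearman
correlation from the Gaussian copula, so continuous–continuous targets
use the bivariate-normal closed form (latent = 2 sin(π ρ/6)). Binning
attenuates, so the two headline associations are calibrated by bisection
over simulation with common random numbers (`calibrateLatentCorrelation`,
`calibrateCohortConfig`): first the cell-density/HLA-DR latent entry so
the binned ICsc attains Spearman 0.30 with HLA-DR, then a shared
nerve-severity loading (positive on tortuosity and reflectivity,
negative on nerve density) so the *total* score also attains Spearman
0.30 — the source reports 0.3 for both, and a single subscore-level
plant provably attenuates the total's correlation to about 0.2, which is
why both stages exist. Only correlations reported as significant are
planted; all other entries are zero (the full matrix is not published),
and the filled matrix is repaired to the nearest correlation matrix
(Higham projection via `Matrix::nearPD`) before Cholesky simulation. The
calibration uses the NAIDED marginals (the dominant group; subscore
marginals are nearly identical across groups) with 20,000 draws per
bisection step and is deterministic given its seed.

The generator does **not** fit anything to patient-level data, does not
model treatment or longitudinal structure, and reproduces between-group
contrasts only through the per-group marginals; subgroup-specific
correlation differences are not planted.

# The synthetic frame renderer

Frames are rendered on the package-wide raster convention (8-bit
grayscale, origin top-left, x rightward, y downward, 0-based pixels).
Nerves are planted as edge-to-edge chords plus two random sinusoidal
harmonics of perpendicular displacement, tapered at the endpoints; the
displacement amplitude is the tortuosity dial (0 = exactly straight),
and expected tortuosity is monotone in it. Strokes have a Gaussian
cross-section (σ = 1.2 px) with peak intensity `nerveContrast`; cells
are isotropic Gaussians (σ = 3 px) with 2–4 short radial processes
mimicking dendritiform morphology (maturity is not modelled — the
grading counts all cells as one class). Cell centers are
rejection-sampled with a minimum separation so ground truth is
unambiguous. The composite is blurred, Gaussian noise added, and clipped
to 0–255, with a warning when contrast exceeds the range. The ground
truth records every planted object with exact coordinates, per-nerve
arc length and tortuosity; reflectivity ground truth is the
contrast/background ratio. Intensity statistics of real instruments are
not published, so contrast defaults (nerve 100, cell 80, background 50,
noise SD 5) are free parameters chosen to resemble typical sub-basal
frames; passing tests demonstrate correctness on this geometry, not
photorealism.

# Bead calibration

Quantitative fluorescence conversion follows the standard QIFI-style
convention: ordinary least squares of log10(assigned antibody-binding
capacity) on log10(bead MFI) over at least three bead populations,
with a warning below R² = 0.98; samples convert as
`AUF = 10^(intercept + slope·log10(MFI − background))`. The exact AUF
definition of the source assay is not published, so this bead-regression
convention is adopted and documented. Background defaults to 0 when no
negative/isotype control is supplied; samples at or below background
convert to 0 and are flagged rather than dropped. Weighted fits are out
of scope.

# Statistics

Spearman correlations are tie-corrected (Pearson on midranks) with
pairwise-complete deletion; per-cell sample sizes are reported so
missing-data handling is auditable (whether the source used pairwise or
listwise deletion is unstated — pairwise is this package's choice).
Two-sided p-values use exact permutation enumeration for pairwise n ≤ 10
(a compiled kernel enumerates all n! rank assignments) and the
t approximation above. Mann-Whitney comparisons use midranks, exact
enumeration when n₁+n₂ ≤ 12 without ties, and otherwise the normal
approximation with tie and continuity corrections; by enumeration, that
approximation stays within 0.0055 of exact everywhere the exact
two-sided p is below 0.1 at n₁ = n₂ = 6, and deviates by at most ~0.016
mid-range where no significance decision changes. Raw p-values are
masked at α = 0.05 by default, mirroring the source analysis; a
Benjamini-Hochberg option is available but off by default — fidelity
first, rigor as an option. Constant variables yield undefined (missing)
correlations, never zero. Stratifications follow the published cuts:
low inflammation ICsc 0–2 versus high ICsc 3 (the source figure caption
mentions "IC-3 to IC-4", but the grading defines 3 as the maximum, so
high = IC-3 only), and extreme totals ≤ 2 versus ≥ 5.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-chord polylines are
excluded from tortuosity with a warning (an empty frame reports 1 by
convention); empty strata make comparisons "not computable" rather than
erroring; a zero background median is an error for the reflectivity
index. All randomness flows from one root seed split per stage, so
cohorts, frames and pipeline manifests are byte-reproducible.

The test and verification sizes are the package's own choices: 20
replicate cohorts of 214 eyes for recovery checks (Monte-Carlo error on
the mean total score ≈ 0.016, far inside the ±0.2 band), 1,000 null
replicates at n = 214 for the type-I-error check, 100 replicates for
bead-slope recovery, and 20 frames for detector recall. The measured
power of the high/low-ICsc HLA-DR comparison at the planted Spearman 0.3
is about 0.88 with a high stratum of ~26 eyes; the corresponding test
therefore asserts direction in ≥95% and significance in ≥75% of 40
replicates.

# Known limitations

Synthetic cohorts share only the published moments and planted
correlations with any real population; unreported pairwise associations
are absent by construction, so null results on unplanted pairs say
nothing about real data. The renderer omits epithelial texture, stromal
structures and instrument artefacts. Nerve branch topology, dendritic
maturity subclassification, FCS listmode parsing and gating, regression
modelling and any re-derivation of inter-rater reliability are out of
scope.

# A minimal session

```{r example, eval = FALSE}
cfg <- calibrateCohortConfig(table1Default(), seed = 1)
cohort <- generateCohort(cfg, seed = 1)
cr <- spearmanMatrix(cohort, c("age", "oxford", "schirmer_mm", "tbut_s",
                               "ic_sub", "nd_sub", "nm_sub", "tivcm",
                               "hla_dr_auf"))
significantEdges(cr)
compareHlaByIcsc(cohort)
runPipeline(cfg, seed = 1, outDir = "ivcm-run")
```
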