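---
title: "Quantitative adipose phenotyping: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative adipose phenotyping: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipophen)
```

`adipophen` implements the quantification stages of a murine
cardiometabolic phenotyping study as reusable, tested components: whole-body
micro-CT fat segmentation, adipocyte morphometry, stain percent-area
scoring, brown-fat FDG-PET uptake, indirect-calorimetry summaries, and
relative expression normalization. This vignette explains the models and
procedures, the parameters that matter and their defaults, what the
synthetic phantoms do and do not emulate, and the numerical choices made
where the underlying protocols leave the implementation open.

## CT body-fat segmentation

The measurement answers one question: what percentage of the body volume
(excluding air) consists of fat-density tissue?

The pipeline, in `ct_fat_pipeline()`:

1. **Hounsfield normalization** (`normalize_to_hounsfield()`): raw scanner
   values are mapped affinely (`HU = slope * raw + intercept`) so that air
   sits near -1000 HU and water at 0 HU. Fat parenchyma falls near
   -100 HU; lean soft tissue near +40 to +80 HU.
2. **Body extraction** (`segment_body()`): Gaussian smoothing at a physical
   sigma of 0.1 mm (converted per axis to voxel units, so anisotropic grids
   are smoothed isotropically in space), a threshold keeping voxels at or
   above -700 HU, and retention of the largest 26-connected component.
   Smoothing before this threshold stabilizes the body outline against
   noise; the -700 HU cut sits far from both air (-1000) and tissue, so the
   body boundary lands in the steep part of the air/tissue transition.
3. **Candidate fat** (`segment_fat()`): voxels inside the body whose
   intensity lies in the closed window [-250, 50] HU. The window is applied
   to the *original* (unsmoothed) intensities by default. This is a
   deliberate choice: on a smoothed image the window's upper bound (50 HU)
   lies deep on the lean side of every fat/lean transition (-100 to +60
   HU), so thresholding after smoothing systematically annexes roughly one
   voxel of lean tissue around every fat structure — on our phantoms a +8
   percentage-point error at typical fat surface areas. Thresholding the
   original volume removes that bias entirely; noise robustness is restored
   by the cleanup below. `threshold_smoothed = TRUE` switches back to the
   all-smoothed variant.
4. **Partial-volume correction**: at air/tissue interfaces the scanner's
   point-spread function mixes air (-1000 HU) with tissue, and the mixture
   passes through the fat window, inflating the estimate. Air regions
   (strictly below -250 HU, speckle-filtered) are therefore dilated by 3
   voxels — the lung, defined as the largest air component strictly interior
   to the hole-filled body, by 3 more — and candidate voxels inside the
   dilated zones are excluded. Dilation is performed in voxel units, not
   mm, and in 3-D by default (`dilate_2d = TRUE` gives the slice-wise
   variant).
5. **Speckle and hole cleanup**: one morphological opening by the 3x3x3 box,
   removal of 26-connected components smaller than 27 voxels (the volume of
   that same structuring element), and filling of enclosed cavities. The
   box opening matters: with realistic noise the lean-tissue intensity
   distribution (mean ~+60 HU) overlaps the window's upper bound, producing
   a partially occupied "fuzz" layer on every flat fat surface. A size
   filter cannot remove fuzz that is connected to real fat, and a
   cross-shaped opening reconstructs it (the fuzz voxels themselves make
   face voxels look interior); the box opening strips it while returning
   flat faces exactly. Hole filling is restricted to candidate voxels
   outside the exclusion zone so that the invariants *final fat ⊆ candidate
   fat ⊆ body* and *final fat ∩ dilated air = ∅* hold unconditionally.
6. **Reporting** (`compute_fat_fraction()`):
   `percent_fat = 100 * |fat| / |body \ air|` — the denominator is the whole
   body volume excluding air.

Connectivity conventions: 26-connectivity for objects, 6-connectivity for
background and holes (8/4 in 2-D), the standard complementary pairing.
Largest-component ties break toward the component first encountered in
column-major order; lung-candidate ties break by lowest centroid z, then y,
then x. All are deterministic.

## Adipocyte morphometry

H&E adipose fields are converted to Rec. 709 luminance and
contrast-stretched linearly between the 1st and 99th intensity percentiles
(`preprocess_he()`); a constant field is returned unchanged with a warning.
Lumina are detected by a white threshold — Otsu's method by default, a fixed
override for reproducing legacy analyses — labeled with 8-connectivity,
filtered at a minimum area of 200 µm² (below any plausible adipocyte
cross-section at 20X; suppresses inter-cellular white speckle), and
optionally pruned of border-touching cells (`segment_adipocytes()`).
Watershed splitting of touching cells is deliberately not applied: the
underlying protocol is plain thresholding, and splitting would change the
size distribution it produces.

`size_distribution()` bins areas into half-open intervals `[e_i, e_{i+1})`
(final bin closed), 500 µm² wide from 0 to 10,000 µm² by default, with an
explicit overflow bin so proportions over all cells always sum to 1. Both
counts and proportions are reported, since published size-frequency plots
use either. The mean is the plain arithmetic mean of per-cell areas.

## Stain percent-area

`quantify_stain_area()` reports `100 * stained / ROI` pixels. Because "a
threshold for red" is not a colorimetric definition, the stain rules are
explicit HSV predicates and every parameter is exposed: picrosirius red is
hue within ±20° of red (wrapped), saturation ≥ 0.3, value ≥ 0.2
(`stain_rule_psr()`); DAB is hue 10-45°, saturation ≥ 0.25, value ≥ 0.2
(`stain_rule_dab()`). ROIs are polygon rasterizations (even-odd rule at
pixel centers, `polygon_roi()`) or full-field.

## PET brown-fat uptake

Sparse hand-drawn axial contours (every 3-4 slices in the source protocol)
are reconstructed into a 3-D ROI by shape-based interpolation
(`interpolate_roi()`): each polygon is rasterized on its own slice with the
even-odd rule at voxel centers, and intermediate slices threshold the
linear interpolation of the two neighboring slices' signed Euclidean
distance maps at zero. Interpolating distance maps rather than masks gives
the geometrically expected intermediate shapes (a 10 px and a 20 px circle
yield a 15 px circle halfway) and reproduces each input contour exactly on
its own slice. Slices outside the contoured range stay empty. Distance
maps are computed in pixel units and assume near-isotropic in-plane
spacing — a documented limitation.

Uptake (`compute_pet_uptake()`) is
`%ID/g = 100 * mean activity concentration / (injected dose * density)`
with tissue density fixed at 1 g/mL by default so ROI mass equals ROI
volume (the standard small-animal convention; configurable). No radioactive
decay correction is applied by default — the quantity is whatever the
calibrated volume encodes — and the gamma-count analogue
(`gamma_uptake()`) is `100 * counts / (injected counts * tissue weight)`.
`correlate_pet_gamma()` regresses gamma on PET by ordinary least squares
and reports slope, intercept, Pearson r, r², and the two-sided slope
p-value — the standard cross-validation of image-derived uptake against
excised-tissue counting.

## Indirect calorimetry

Samples are labeled diurnal if their clock time falls in the half-open
interval `[lights_on, lights_off)`, nocturnal otherwise; wrap-around
schedules are handled (`partition_cycles()`). RER is `VCO2/VO2`. Energy
expenditure converts mass-specific gas exchange (mL/kg/h) to absolute L/h
via body mass and applies, by default, the Lusk-type equation
`EE (kcal/h) = 3.815*VO2 + 1.232*VCO2` — the equation family implemented by
CLAMS-class analysis software, whose exact formula is proprietary; the
abbreviated Weir equation (`3.941*VO2 + 1.106*VCO2`) is available via
`formula = "weir"`, and every result carries the formula it used.
`summarize_cycles()` reports per-phase arithmetic means and totals and can
drop a leading acclimatization window (`drop_acclimation_h = 24` mirrors
the usual 24 h chamber acclimation).

## Relative expression

`fold_change()` implements delta-delta-Ct: per sample
`dCt = Ct(target) - Ct(reference)` (reference defaults to 18s), baseline =
arithmetic mean control dCt, `fold = 2^-(dCt - baseline)`. Normalizing to
both the reference gene and the control group makes the control-group
geometric mean fold exactly 1. The choice of the control *mean* as baseline
(rather than a single calibrator sample) is the symmetric option when no
calibrator is designated. cDNA dilution factors are treated as
pre-analytic and are not corrected in Ct space. `normalize_densitometry()`
divides each lane's target intensity by its loading control (β-actin by
default) and optionally rescales so the control-group mean is 1.
`fold_change_ci()` builds the fold interval from a Welch t interval on the
dCt difference, which propagates baseline uncertainty correctly.

## Synthetic phantoms and what they show

Every generator is a pure function of its parameters and a seed, and every
phantom ships machine-readable ground truth computed from the generating
geometry, never from the rendered data.

**CT** (`make_ct_phantom()`): an ellipsoidal soft-tissue body (+60 HU) in
air (-1000 HU) with two -900 HU lung cavities, fat (-100 HU) as a
subcutaneous shell under a 4-voxel skin rind plus interior blobs, additive
Gaussian noise (default sigma 20 HU), and optionally a 1-voxel interface
blur emulating the scanner's partial-volume effect. The default grid is
96x96x128 voxels at 0.2 mm — a mouse-scale field of view that runs in
seconds. Geometry choices made once for realism: the shell band is at least
3 voxels (0.6 mm) thick, because sub-voxel fat sheets are neither
anatomically typical of obese mice nor resolvable at this voxel size;
interior blobs are 1.2-2.2 mm lobes; fat is kept clear of air interfaces
(skin rind; 7-voxel lung margin) the way subcutaneous and gonadal depots
are, so the recorded truth reflects tissue volumes rather than interface
voxels whose class is genuinely ambiguous. The exact target fraction is
hit voxel-for-voxel by construction. Validated recovery: across 20
phantoms spanning 5-50% true fat at default noise, the absolute error
stays within 2 percentage points with perfect rank agreement (the
acceptance suite recomputes this). What the phantom does *not* emulate:
beam hardening, bed artifacts (inputs are assumed bed-free; a pre-computed
body mask can be supplied), anatomy beyond ellipsoids, and correlated
reconstruction noise — passing tests bound algorithmic error, not
scanner-specific artifacts.

**Histology** (`make_adipocyte_mosaic()`, `make_stain_field()`): mosaics
are multiplicatively weighted Voronoi tessellations with one centroidal
relaxation pass, target areas drawn lognormal, bright lumina (~230) and
dark membranes (~60); the field size is calibrated in a second pass so the
realized mean lumen area tracks the requested mean. Truth is the exact
per-cell lumen pixel count, and lumen areas plus membrane pixels partition
the field. Stain fields paint exactly `round(f * ROI)` pixels — chosen as
the top quantile of a smoothed Gaussian random field, so blobs look
organic while the stained fraction is exact — in reference colors whose
jitter stays inside the detection windows. Not emulated: chromatic stain
variability, out-of-focus blur, touching-cell ambiguity, crown-like
structures.

**PET** (`make_pet_phantom()`, `make_pet_gamma_cohort()`): a hot ellipsoid
(default 20 %ID/g equivalent) over low background with Gaussian (or
Poisson) noise; contours traced from the true ellipsoid every 3 slices
plus the extreme visible slices, as an annotator would. The cohort
generator gives each subject one true uptake, measures it through the full
image pipeline, and derives the paired gamma count from the same truth
with 2% measurement noise.

**Calorimetry and tables** (`make_clams_trace()`, `make_qpcr_table()`,
`make_densitometry_table()`): two-phase traces with a within-phase
sinusoid recentered so the phase means are *exact* at zero noise
(nocturnal VO2 elevation as in mice, RER 0.82 light / 0.95 dark); Ct
tables constructed so target genes have exactly the specified fold
changes before noise.

## The study orchestrator

`run_study()` ties the stages into a two-group synthetic study
(`study_config()` holds every parameter; defaults contrast an obese
control against a lean test group with higher brown-fat uptake, UCP-1
fold 10, and elevated energy expenditure, at 3 subjects per group and
reduced grid sizes — 64x64x96 CT, 48³ PET — chosen so a full study runs in
well under a minute). Per-stage seeds are derived deterministically from
the master seed, outputs are CSV/JSON with no timestamps, and a rerun with
the same configuration is byte-identical. Group summaries report mean ±
SEM; p-values come from Welch's t-test via `stats::t.test()` and are
labeled as such. The orchestrator adds no computation of its own.

## Numerical and degenerate-input conventions

* Threshold inclusivity: fat window closed `[-250, 50]`; body `>= -700`;
  air strictly `< -250` ("between" read as inclusive — measure-zero on
  continuous data).
* Erosion treats out-of-grid voxels as background (masks erode at the grid
  boundary); dilation is its adjoint on the grid interior.
* An empty above-threshold set in body segmentation, an empty ROI, a zero
  denominator, a zero rescale slope, equal lights-on/off times, vo2 ≤ 0,
  and a control-free expression table are all classed errors
  (`adipophen_error` subclasses), not silent results; a missing lung is a
  warning with an empty mask, since fat correction can proceed without it.
* All randomness flows through per-call seeds; generators restore the
  caller's RNG state.

## Known limitations

* The CT method measures fat-*density* volume, not chemical adiposity; at
  severe noise (sigma well above 30 HU) the lean/fat window overlap becomes
  the dominant error term for any threshold method.
* Distance-map interpolation assumes in-plane isotropy and simple
  (non-self-intersecting) contours; branching structures between distant
  contours are merged by the signed-distance average, as with any
  shape-based method.
* Energy-expenditure absolute values depend on the chosen calorimetric
  equation; comparisons across software require matching formulas.
* The bed-removal and PET/CT registration steps of the source workflow are
  out of scope: volumes are assumed bed-free and co-registered.
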