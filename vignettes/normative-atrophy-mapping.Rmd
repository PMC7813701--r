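---
title: "Normative gray-matter atrophy mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative gray-matter atrophy mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxnorm)
```

## The problem and the model

Regional gray-matter (GM) loss beyond what normal aging explains is the
imaging signature of most neurodegenerative diseases, but visual reading of
it is unreliable and ignores age and sex. `voxnorm` implements the
population-normative answer from voxel-based morphometry (VBM): reduce
every scan to a spatially normalized, modulated, smoothed GM map; summarise
a healthy cohort as voxel-wise normative mean and SD maps per (age, sex)
cell; and score a patient as the voxel-wise z-deviation

$$z(v) = \frac{g(v) - \mu(v; a, s)}{\sigma(v; a, s)},$$

displayed only where $|z| > 2.5$ and fused in color with the structural
scan. The z-map is descriptive, not inferential: the fixed 2.5 SD cut is a
reading aid, and no multiple-comparison correction is applied by design.

The assumptions are those of normative modelling generally: voxel
correspondence across subjects after normalization, approximate Gaussian
voxel distributions within an (age, sex) window so that SD units are
interpretable, and a cohort that actually represents the scored patient's
population.

## The preprocessing chain and its simplifications

`preprocessSubject()` composes: brain masking (Otsu threshold, largest
6-connected component, morphological closing), K = 3 Gaussian-mixture EM
tissue segmentation on intensities (GM = the middle-intensity class
posterior; quantile initialization, so the fit is deterministic),
9-parameter affine registration to a reference (translation, per-axis
log-scale, rotation; Nelder-Mead on the mean-squared intensity difference
over a coarse-to-fine schedule), trilinear resampling to the template grid,
Jacobian modulation, and Gaussian smoothing.

Two deliberate simplifications:

* **Affine-only normalization.** Production VBM pipelines use nonlinear
  warps; an affine stand-in keeps the package self-contained and exactly
  testable (translation and scale recovery are verified against programmed
  ground truth). Users with externally preprocessed, nonlinearly normalized
  maps ingest them through the bypass `asPreprocessedGM()`, which leaves
  already-smoothed maps untouched (idempotence is tested).
* **Global modulation.** For an affine subject-to-template transform the
  Jacobian is the single factor $1/|\det A|$; total GM volume before and
  after normalization agrees within 1 % in the tests. With nonlinear warps
  the determinant would be a field; the bypass again makes this moot.

One chain, two uses: templates and single subjects must be preprocessed
identically, otherwise systematic differences between the chains appear as
spurious z. This is why the z-calibration tests feed template cohort *and*
test subjects through the same route (the generator bypass), while the full
T1 chain is validated separately — for segmentation accuracy (Dice > 0.95
against phantom labels), registration recovery, volume conservation, and an
exactness oracle: on an aligned, noise-free plateau phantom the chain
output equals `gaussianSmooth()` of the ground-truth GM to machine
precision.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| smoothing FWHM | 8 | mm | the standard VBM kernel; sets the scale of detectable effects |
| z cut | 2.5 | SD | strict inequality; a voxel at exactly 2.5 is not shown |
| age window half-width | 2 | years | inclusive at both ends; ages floored to integer years |
| template age range | 18–75 | years | outside it `mapSubject()` refuses with an unsupported-age error |
| SD floor | 1e-6 | GM units | voxels with near-zero normative SD are excluded from the mask rather than clamped — a z there is meaningless |
| GM mask mean threshold | 0.1 | GM units | grand-mean absolute threshold, the usual VBM masking convention |
| QC cutoff | 0.95 | fraction | minimum share of colored voxels on brain tissue |
| color saturation `zMax` | 10 | SD | bounded color bar; overlay alpha 0.6 |

Sample SD uses denominator $n-1$ (verified against a hand example): the
window is a sample from the normative population. Windows need at least 2
subjects (hard error; SD undefined below) and warn below 20 (small-$n$ SDs
are unstable at the cohort age extremes).

## The synthetic cohort: what it emulates and what it does not

`phantomSpec()` defines the reference study conditions, chosen once:
a 32³ grid of 4-mm voxels holding a spherical-shell brain — WM core to
30 mm, GM ribbon 30–50 mm, CSF rim to 54 mm, logistic tissue boundaries of
3 mm so smoothing sees realistic partial-volume profiles — with baseline GM
amplitude 0.8, linear GM decline of 0.3 %/year from age 18 (a
literature-typical VBM aging effect), +0.02 offset for sex M, iid voxel
noise SD 0.03 on the GM map, and T1 tissue intensities
bg/CSF/GM/WM = 0.05/0.25/0.55/0.85 with noise SD 0.02. The default cohort
spans ages 16–77, both sexes, 6 per cell — 744 subjects, matching the scale
of a realistic normative sample. All generation is seed-deterministic,
byte-for-byte.

At these conditions each template window holds 30 subjects. Scoring an
independent null phantom against templates *estimated* from 30 maps gives
slightly heavier-than-normal tails (a Student-t effect,
$\sqrt{1 + 1/n}\,t_{n-1}$), so the expected $|z|>2.5$ exceedance is ~2 %
rather than the asymptotic 1.24 %; the acceptance band [0.5 %, 3 %] covers
this plus smoothing-induced correlation. Measured: ~1.4 %.

What the phantom does **not** emulate — and hence what passing tests do not
show about real data: anatomy (no gyri, no hemispheric structure), scanner
artifacts and bias fields, registration failure modes of real heads,
nonlinear deformation, age-dependent T1 contrast (the rendered T1 is
age-independent; aging lives in the GM maps, which is what the z-machinery
consumes), and spatially correlated biological variability. Calibration
results transfer to real cohorts only to the extent those factors are
handled by the (bypassed) production preprocessing.

Lesion injection (`injectAtrophy()`) subtracts `effect × σ(v)` inside a
sphere (or with Gaussian falloff), clipping at zero GM — so the injected
dose is calibrated in the same SD units the z-map reads out, and recovery
(mean lesion z within ±0.5 of −2/−3/−4, monotone in dose) is a direct
end-to-end check.

## Numerical choices

* All floating arithmetic is double precision; NIfTI output defaults to
  float32, but template libraries are stored as float64 uncompressed `.nii`
  plus a JSON manifest so save/load round trips are bit-for-bit and rebuild
  runs are byte-identical (gzip would embed timestamps).
* Smoothing kernels are truncated at 4σ per axis with zero padding — the
  common VBM convention; constants are preserved away from boundaries and
  total mass is conserved on padded grids (tested at 1e-8).
* Resampling is pull-style trilinear (or nearest) with a declared fill
  value; the identity transform on an identical grid returns the input
  exactly, with no interpolation.
* Thresholding happens **after** back-transformation to subject space:
  interpolating a thresholded, discontinuous field would smear its edges.
* EM degenerate inputs (fewer distinct intensities than classes) are hard
  errors; non-convergence returns the best-so-far fit with a warning; class
  SDs are floored at 0.1 % of the intensity range so noise-free plateau
  images remain fittable.
* McNemar's test auto-switches: exact binomial below 25 discordant pairs,
  continuity-corrected χ² above (both available explicitly); with no
  discordant pairs the result is flagged with p = 1. Reported percentages
  round half away from zero to one decimal.
* The registration returns its initialization unchanged when that already
  attains (near-)zero cost, so perfectly aligned inputs stay exactly
  aligned.

## Design decisions where the design was open

* **QC brain mask.** The alignment QC asks what fraction of colored voxels
  lies on brain. Findings smoothed with an 8-mm kernel legitimately extend
  past the tissue edge, so the QC mask is the head mask dilated by the
  smoothing FWHM. Under this choice aligned phantoms score ≈ 0.99 and a
  20-mm misregistration scores ≈ 0.75–0.92, cleanly across the 0.95 cutoff.
* **GM mask construction.** Built from the template library itself (grand
  mean > 0.1 and pooled SD above the floor) rather than from an external
  atlas — self-contained and division-safe.
* **Integer template ages.** Subject ages are floored and templates indexed
  by integer age; a ±2-year inclusive boxcar window follows directly.
* **Phantom ages below 18.** The cohort spans 16–77 while templates cover
  18–75, so the boundary windows (e.g. age 18 uses 16–20) are fully
  populated; the linear decline simply extrapolates above baseline for
  ages below the reference.
* **Kernel width convention.** Smoothing is specified as FWHM, the
  convention of the major VBM packages; `fwhmToSigma()` makes the
  conversion explicit rather than implicit.

## Problem sizes used in the checks

Template math is verified against brute-force per-voxel loops on 8³ grids
(all 116 windows); z-calibration uses 50 null phantoms and lesion recovery
6 phantoms per dose at the reference 32³ conditions; the full T1 chain is
exercised on a handful of 32³ registrations. These sizes make the whole
suite run in about a minute while leaving every claim tested at the
conditions the defaults define.

## Known limitations

Affine-only normalization; no covariate adjustment (total intracranial
volume, scanner site); boxcar rather than kernel-weighted age windows; no
longitudinal change maps; descriptive thresholding without voxel-wise
inference; DICOM ingest limited to explicit-VR little-endian single-frame
series. The bypass interface is the intended route around the first two for
production-grade preprocessing.
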