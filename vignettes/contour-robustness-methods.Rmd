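---
title: "Methods: quantifying inter-reader contouring effects on CT texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying inter-reader contouring effects on CT texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texrob)
```

## The problem

Radiomic texture features are computed from a manually segmented region of
interest (ROI), so two readers contouring the same lesion produce two
different feature values. For liver metastases on contrast-enhanced CT,
boundaries are often blurred and low-contrast, making this inter-reader
component of variability substantial. `texrob` implements the full
analysis chain needed to measure it: it quantifies how well two readers'
contours agree (Dice coefficient, average Hausdorff distance), propagates
both contours through a fixed texture-extraction protocol, and summarises
each feature's stability (mean relative change, intraclass correlation),
for whole-lesion 3D ROIs, single-slice 2D ROIs and simplified circular
ROIs.

Because clinical CT segmentations generally cannot be redistributed, the
package ships a synthetic-cohort generator that plays the role of the
data: textured lesion phantoms with a known ground-truth contour and two
simulated readers. All statements the test suite makes about the pipeline
are statements about this synthetic cohort.

## The synthetic cohort

### Lesion phantoms

Each lesion is a star-shaped region around a center: a sphere of diameter
$D$ whose radius is modulated by a smooth low-order random field on the
sphere, $R(u) = \tfrac{D}{2}\,(1 + \varepsilon f(u))$ with
$\max|f| = 1$. The intensity volume is

$$ I(v) = \mu_{bg} + (\mu_{les} - \mu_{bg})\, M_\sigma(v) + T(v), $$

where $M_\sigma$ is the truth indicator smoothed by a Gaussian of width
`boundary_blur_sigma` (the blurred, partial-volume-like interface) and $T$
is a stationary correlated Gaussian texture field, built by Gaussian
smoothing of white noise and rescaled analytically so its marginal
standard deviation equals `noise_sd` exactly. Intensities are clamped to
the CT-representable range $[-1024, 3071]$ HU.

Default population ranges, drawn uniformly per lesion:

| parameter | default | rationale |
|---|---|---|
| diameter | 10--80 mm | the lesion-size range of the emulated study population |
| background mean | 110 HU | portal-venous liver parenchyma |
| lesion mean | 50--70 HU | plausible hypodense metastasis values |
| texture correlation length | 3--6 mm | visible CT texture scale |
| texture sd | 10--20 HU | moderate noise/texture amplitude |
| boundary blur | 1--2 mm | blurred lesion interface |
| shape irregularity | 0.03--0.08 | mildly non-spherical lesions |
| in-plane spacing | 0.7--0.9 mm | abdominal CT reconstruction |
| slice thickness | 2.5 or 3 mm | abdominal CT reconstruction |

The texture model is a deliberate stand-in: a stationary Gaussian field is
the simplest process with non-degenerate co-occurrence and run-length
statistics. It does not claim to reproduce tumour biology, necrosis,
rim enhancement, or scanner-kernel effects, so cohort-level feature
*values* should not be read as clinical reference values; only the
*relative* behaviour of features under contour perturbation is meaningful.

### Simulated readers

A reader's contour is the truth boundary displaced along the outward
radial direction by

$$ \Delta(u) = b + \sigma_j\, g_1(u) + s_{pv}\, \Delta z\, |\cos\theta|\, g_2(u), $$

with $b$ the signed systematic bias (`radial_bias`, mm), $g_1, g_2$
independent smooth zero-mean unit-variance random fields on the sphere
(angular correlation scale `jitter_smoothness`), $\sigma_j$ the isotropic
jitter amplitude (`radial_jitter_sd`, mm), and the last term a slice-wise
partial-volume component: it grows with $|\cos\theta|$, i.e. where the
surface normal approaches the slice axis, scaled by the slice thickness
$\Delta z$ and `partial_volume_scale`. This reproduces the clinical
observation that the peripheral axial slices of a lesion are the hardest
to contour consistently, which is what makes single-slice 2D ROIs agree
better than 3D ROIs. A reader with zero jitter is perfectly consistent
and reproduces the truth mask exactly.

The displaced region stays star-shaped about the lesion centroid, which
structurally keeps each reader mask one connected component; a draw
extreme enough to shrink the boundary radius below half a voxel anywhere
is rejected as a perturbation error (and redrawn deterministically during
cohort generation).

Defaults were calibrated once against the inter-reader agreement ranges
reported for CT liver metastases: `radial_bias` $\pm 0.3$ mm (reader 1
slightly over-, reader 2 slightly under-segmenting), `radial_jitter_sd`
0.8 mm, `jitter_smoothness` 0.8 rad, `partial_volume_scale` 1.2. At the
study scale (70 lesions) these give a median 3D Dice near 0.8 (clinical
reports: about 0.76), better 2D than 3D agreement on both indices, and a
negative Dice-versus-Hausdorff rank correlation. They are fixed defaults,
not tuning knobs of the test suite.

### Reproducibility

Every random element is driven by explicit seeds. `generate_cohort`
derives per-lesion and per-reader seeds from one master seed with a fixed
splitting scheme, so a cohort regenerates bit-identically; package
functions restore the caller's RNG state.

## ROI derivation

* **2D ROI**: the axial slice with the largest foreground area (mm^2);
  ties break to the lowest slice index. "Most representative" is
  operationalized as "largest", since reader judgement cannot be encoded.
* **Enclosing circle**: the minimum enclosing circle (Welzl's algorithm,
  in physical mm) of the 2D ROI's voxel centers, rasterized by
  center-inclusion (a voxel belongs to the circle iff its center is
  within the radius). Structurally a superset of the 2D ROI.
* **Inscribed circle**: centered on the foreground voxel maximizing the
  distance to background (ties: lexicographic voxel index), with radius
  equal to that distance minus half the in-plane voxel size, i.e. the
  distance to the nearest background voxel edge; the rasterization is
  intersected with the ROI, making the subset property structural.

Circles are computed in millimetres, so anisotropic in-plane spacing is
handled; two 2D ROIs are always compared in-plane, even if the two
readers picked neighbouring slices.

## Texture extraction

Intensities are discretized over a fixed window of 480 grey levels, from
-200 to 279 HU, into 32 uniform bins of 15 HU (left-closed bins, the last
bin right-closed; out-of-window values are clamped to the extreme bins
and counted). No resampling or filtering is applied: anisotropic voxels
are used as-is and offsets are in voxel steps.

Co-occurrences are counted at offset 1 in all unique directions (13 in
3D, 4 in-plane in 2D), symmetrically (both orderings), and the
per-direction count matrices are **summed** into one matrix before
normalization; run-length matrices are likewise accumulated over
directions, so each voxel contributes one run per direction and
$\sum_{ij} j\, r_{ij} = n_{dir}\, n_{voxels}$. Per-direction averaging is
available for the co-occurrence matrix as a non-default option. Under the
summed convention, run percentage divides the total number of runs by
$n_{voxels} \times n_{dir}$.

The 21 co-occurrence and 11 run-length features follow the IBSI reference
formulas (entropies in bits). Naming follows the radiomics-software
convention in which `Homogeneity` is the IBSI *inverse difference* and
`Homogeneity2` the IBSI *inverse difference moment*. On a zero-variance
(single-grey-level) matrix, `Correlation`, both information measures of
correlation and `InverseVariance` are undefined and return `NaN`; the
robustness statistics exclude non-finite values per lesion and report the
count used. Morphology features are the foreground voxel count, the
volume in cm^3, and the maximum 3D diameter (max pairwise distance
between surface voxel centers, computed exactly after pruning to
per-line extreme voxels).

## Agreement and robustness statistics

* **Dice coefficient**: $2|A \cap B| / (|A| + |B|)$.
* **Average Hausdorff distance**: boundary voxels are foreground voxels
  with a face-adjacent background neighbour (6-connectivity in 3D,
  4-connectivity in-plane in 2D); the statistic is the symmetric average
  of nearest-boundary distances in mm,
  $[\sum_{p \in \partial A} d(p, \partial B) + \sum_{q \in \partial B} d(q, \partial A)] / (|\partial A| + |\partial B|)$.
  The symmetric form is chosen so the measure is invariant to argument
  order. Nearest-neighbour searches are exact (windowed by slice for
  speed, with certification that no closer point was excluded).
* **Relative change**: $(RF_{R1} - RF_{R2}) / RF_{R1}$, signed, reader 1
  as reference; lesions with a zero or non-finite reference are excluded
  and counted. The **mean relative change** averages the *absolute*
  changes and is reported in percent --- the only aggregation consistent
  with reporting nonnegative MRC percentages while individual changes are
  signed.
* **ICC(2,1)**: single-rater, two-way random-effects, absolute-agreement
  intraclass correlation from the ANOVA mean squares,
  $(MS_R - MS_E) / (MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E))$, with
  the consistency form available behind an option. Bands: poor
  $\le 0.50$, moderate $\le 0.75$, good $\le 0.90$, excellent $> 0.90$.
* **Robust-feature rule**: ICC $> 0.90$ **and** MRC $< 10\%$, strict
  inequalities, so boundary values are rejected.
* Companion tests are the two-sided Wilcoxon signed-rank test (zero
  differences dropped; exact null up to 25 pairs, normal approximation
  with continuity correction beyond), Spearman's rank correlation
  (average ranks, t-approximation p-values) with Evans strength labels,
  ordinary least-squares size-versus-agreement fits, and the circular-ROI
  comparison (inter-reader MRC versus the MRC of replacing reader 1's
  manual 2D ROI by each circle, reader 1 as reference). No multiplicity
  correction is applied; p-values are reported raw at the 0.05 level.

Lesions whose maximum axial (within-slice) diameter is below 10 mm are
excluded before analysis; a lesion of exactly 10 mm is retained. In the
pipeline the exclusion is measured on reader 1's mask.

## Numerical and design choices

* Voxel indices are 0-based in physical terms: voxel $(i,j,k)$ (1-based
  in R) sits at $(i-1, j-1, k-1) \times$ spacing, voxel-center
  convention throughout.
* Quartiles use linear interpolation (R type 7).
* MRC is computed on raw feature values, without outlier truncation, and
  ICC on raw (not log-scaled) values.
* The "main lesion" receiving circular ROIs is the largest reader-1 3D
  volume per patient; in synthetic mode every lesion is its own virtual
  patient.
* The per-direction *summed* matrix convention (rather than per-direction
  feature averaging) is adopted because merged-matrix behaviour is what
  "all directions considered" software defaults produce; the alternative
  is exposed as an option, not a default.

## Problem sizes used by the checks

The package's own verification uses: exhaustive brute-force oracles on
random ROIs up to $6^3$ voxels (matrix builders) and up to $10^3$ voxels
(surface distances); a 70-lesion synthetic cohort at the default
population ranges for cohort-level properties; 500 simulated lesions for
the ICC consistency check. These sizes are the package's verification
protocol, chosen so the whole suite runs on a desk-scale machine.

## Limitations

Passing tests demonstrate correctness of the implemented statistics and
qualitative fidelity of the simulated reader mechanism; they cannot show
that the synthetic phantoms span the heterogeneity of real metastases
(necrosis, rim enhancement, confluence, reconstruction-kernel effects are
all absent), nor that feature robustness rankings transfer to any
specific scanner protocol. Star-shaped lesions cannot represent strongly
concave tumours. The reader model displaces boundaries radially and
cannot emulate topological disagreements (e.g. a reader splitting one
lesion into two).
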