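---
title: "Methods: quantifying strain-driven cytoskeletal and chromatin remodelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying strain-driven cytoskeletal and chromatin remodelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scleromech)
```

## The problem

Scleral fibroblasts live in the collagenous wall of the eye and are cyclically
stretched by the pulsatile intraocular pressure (IOP). In culture, that load
is reproduced by applying equibiaxial cyclic tensile strain to cells on
flexible membranes, and the cellular response is read out from fluorescence
micrographs: cytoskeletal fibre alignment, cell and nucleus geometry, and
chromatin texture. `scleromech` implements the full quantification chain —
the mechanics that set the strain amplitudes, the image metrics, and the
group statistics — together with a ground-truthed synthetic image generator
so that every stage can be validated against known inputs.

## Mechanics: from IOP to a strain band

The eye globe is approximated as a thin-walled pressurised sphere. The
in-wall (hoop) stress is the Young–Laplace expression

$$\sigma = \frac{p\,r}{2t},$$

with internal pressure $p$, globe radius $r$ and wall thickness $t$. Stress
becomes strain through a Young's modulus $E$; because collagenous tissue
strain-stiffens, a modulus *range* $[E_\min, E_\max]$ is used, producing a
strain band: the stiff endpoint gives the lower strain bound
$\varepsilon_\min = \sigma/E_\max$ and the compliant endpoint the upper bound
$\varepsilon_\max = \sigma/E_\min$.

```{r mechanics}
geom <- ocular_geometry(radius = 16.2e-3, wall_thickness = 1.6e-3)  # bovine
phys <- strain_band(loading_regimen(mmhg_to_pascal(27), 1e6, 7e6), geom)
path <- strain_band(loading_regimen(mmhg_to_pascal(60), 1e6, 7e6), geom)
c(phys = format_percent(c(phys$strain_min, phys$strain_max)),
  path = format_percent(c(path$strain_min, path$strain_max), 1))
```

A healthy baseline IOP of 27 mmHg (3.6 kPa) over a 1–7 MPa modulus range
yields a physiological band of 0.26–1.8 % strain; a glaucomatous 60 mmHg
(8 kPa) yields 0.6–4 %. Conversions use 133.322 Pa/mmHg; `format_percent()`
defaults to two significant figures (the physiological band's convention)
with one significant figure conventional for the pathological band. The 1 Hz
waveform is metadata only — loading is applied by hardware, so no
time-domain simulation is performed. Thin-shell theory ignores regional
wall-thickness variation and asphericity; those limitations are inherited,
not remedied, here.

## Fibre anisotropy

Cytoskeletal alignment is scored from the image-gradient nematic tensor,
equivalently to the published FibrilTool protocol. At each pixel of the
region of interest the local fibril direction is the unit vector
perpendicular to the finite-difference intensity gradient; its outer product
is accumulated with weight equal to the squared gradient magnitude, and the
averaged tensor is normalised to unit trace. The anisotropy score is the
eigenvalue gap $\lambda_1 - \lambda_2 \in [0, 1]$: 0 for isotropic texture,
1 for perfectly parallel fibres; the principal eigenvector gives the mean
orientation (axial, period $\pi$).

Numerical choices: central differences with replicated borders; no
pre-smoothing by default (a Gaussian `smooth_sigma` is available); pixels
whose gradient magnitude falls below $10^{-6}$ times the image intensity
range are skipped as carrying no orientation information, and an image with
no usable gradients at all returns a flagged "undefined-direction" result
with value 0. Magnitude-squared weighting follows standard structure-tensor
practice and suppresses background noise. The score is invariant to affine
intensity rescaling and equivariant under rotation. Tests verify exact
agreement (to 1e-10) with an independent double-loop accumulation on small
images.

One deviation from interactive practice: regions of interest are the
(generated or segmented) cell masks rather than hand-drawn polygons.

## Chromatin condensation parameter (CCP)

Condensed chromatin produces sharp-edged bright foci in DNA-stained nuclei.
The CCP is the Sobel edge density of the nucleus: the 3×3 Sobel magnitude
is computed, binarised at a threshold *relative* to the in-mask maximum
magnitude, and the edge-pixel count is divided by the nuclear pixel area, so
differently sized nuclei are directly comparable.

Choices that the underlying idea leaves open, fixed here: the relative
threshold defaults to 0.15 of the in-mask maximum (exposed as
`ccp_threshold`) — relative thresholding preserves affine-intensity
invariance; a 1 px rim of the mask is excluded so the nuclear outline never
counts as chromatin texture (counting it would reintroduce the
size-dependence the ratio exists to remove); borders are replicated; a
numerical floor of $10^{-9}\max|I|$ keeps convolution round-off on flat
regions from registering as edges. Absolute CCP values are therefore
comparable only within a fixed threshold choice; relative group differences
are the meaningful output.

## Morphometry

Measurements are taken on Z-axis maximum-intensity projections
(`project_max()`). Area is the mask pixel count scaled by the pixel size.
"Eccentricity" follows the cell-shape convention: the width/length ratio of
the moment-equivalent ellipse (minor over major axis length from the second
central moments), so 1 is round and values toward 0 are elongated. This is
deliberately **not** the standard ellipse eccentricity
$\sqrt{1-b^2/a^2}$, which runs in the opposite direction. Moments make the
measure invariant to rotation, translation and uniform scaling; collinear
(degenerate) masks raise an error. For real images without ground-truth
masks a heuristic Otsu + largest-component + hole-fill fallback
(`segment_otsu()`) is provided and flagged as such.

## Synthetic micrographs

`generate_study()` renders single cells and nuclei with known ground truth
under the experiment's 3 groups (unloaded, physiological, pathological) ×
3 timepoints (1 h, 6 h, 24 h):

* **Cells**: elliptical mask; straight fibre segments with a Gaussian cross
  profile, orientations drawn from an axial von Mises distribution (sampled
  on the doubled angle, $\theta \sim \mathrm{vM}(2\mu,\kappa)/2$, because
  fibres have no polarity); overlapping fibres saturate softly
  ($1-e^{-\mathrm{acc}}$). Fibre lengths span the cell, and intensity tapers
  to zero just *outside* the mask: a hard outline step would otherwise
  dominate the magnitude-weighted tensor and cap measured anisotropy well
  below 1 even for perfectly parallel fibres.
* **Nuclei**: elliptical mask at uniform background 0.45 with `n_foci`
  anti-aliased bright discs at `focus_contrast` above background
  (overlapping foci merge by maximum).
* **Noise**: additive Gaussian, clipped to [0, 1]. Poisson shot noise was
  declined for simplicity.
* Canvas 512×512 by default (nuclei may use a tighter crop), 8- or 16-bit
  TIFF output, 0.1 µm/px metadata, optional 8-slice Z-stack mode whose
  maximum projection equals the single-plane render. Everything is
  deterministic given `(config, seed)`.

Group effects enter through two 3×3 tables. `kappa_table` (fibre
concentration) encodes a strong transient alignment response to
physiological strain (κ: 4 → 2 → 0.6 across 1 h/6 h/24 h) and a delayed
response to pathological strain (0.5 → 0.7 → 3) over an unloaded baseline
of 0.5. `foci_table` encodes chromatin condensation: baseline 8 foci,
a mild transient physiological elevation (10 at 1 h), and a strong,
slowly-reverting pathological elevation (28 → 26 → 10). These magnitudes
were fixed from the qualitative time-course they emulate — they are
configurable, not calibrated to any deposited dataset.

Replication is per-channel (`n_cells`, `n_nuclei`): real acquisitions score
every DAPI nucleus but only the subset of cells imaged for a given
cytoskeletal label, so nuclei counts run roughly twice cell counts.

What the phantoms do *not* emulate: confocal point-spread functions and
shot noise, curved or branching filaments, 3D fibre networks, multi-cell
fields, and segmentation error (ground-truth masks are used). Passing tests
therefore validate the measurement chain, not robustness to acquisition
artefacts.

## Statistics

Each (metric, timepoint) family is tested independently across the three
groups, mirroring per-panel comparisons; no cross-timepoint correction is
applied. The assumption gate runs Anderson–Darling normality per group and
Bartlett's k-sample variance homogeneity, both at α = 0.05: all tests
passing selects one-way ANOVA with Tukey HSD pairwise comparisons;
otherwise Kruskal–Wallis with Dunn's rank-based pairwise z tests
(tie-corrected, Bonferroni-adjusted) — the Dunn follow-up is an explicit
extension, since a rank-based omnibus test alone identifies no pairs.
Anderson–Darling requires n ≥ 8; smaller or zero-variance groups route to
the nonparametric path with a warning, and fully constant data short-circuit
to p = 1. Significance is flagged at α = 0.05 with conventional stars
(\* < 0.05, \*\* < 0.01, \*\*\* < 0.001). Box summaries use type-7
quartiles and Tukey 1.5 IQR whiskers, with mean and SD included so either a
quartile or a median ± SD convention can be rendered. Note that a gate of
four serial α = 0.05 tests passes jointly on truly clean Gaussian data only
≈ 0.95⁴ ≈ 81 % of the time — an inherent property of assumption gating,
not a defect.

## Validation problem sizes

The test suite validates at reduced, fixed sizes chosen as this package's
own trade-off between Monte-Carlo precision and runtime: oracle equivalence
on ≤ 32² arrays; noise-floor checks on 256² fields over 100 seeds;
10-point monotonicity grids (anisotropy vs κ, CCP vs focus count) with 3
renders per point at 128/96 px canvases; type-I calibration over 1000
null replicates (3 × 30 observations); and 50 seeded end-to-end runs with
24 cells and 48 nuclei per (group, timepoint) — about one fifth of the
103–145 cells and 227–299 nuclei a full experiment yields per panel,
preserving their ratio — for the significance-pattern recovery check
(physiological anisotropy up at 1 h and 6 h, pathological anisotropy up at
24 h, pathological CCP up throughout). A pathological-vs-unloaded CCP
difference of ~20 % (effect size d ≈ 0.9) is reliably detectable at 48
nuclei per group but not at 10 — the reason nucleus replication is kept
above cell replication, as in the real design.

## Known limitations

Thin-shell mechanics (no regional thickness, no viscoelasticity);
2D projection analysis only (no 3D isosurfaces or local orientation maps);
single-object phantoms; absolute CCP depends on the chosen threshold;
wells and plates are recorded but pooled, not modelled as random effects.
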