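# scleromech

Quantification tools for cyclic-tensile-strain experiments on scleral
fibroblasts — the cells of the eye's load-bearing white outer wall, whose
mechanical environment is dominated by intraocular pressure (IOP) and whose
remodelling responses are implicated in glaucoma.

The package covers the full chain such an experiment needs:

* **Mechanics** — Young–Laplace thin-sphere stress, σ = p·r/(2t), converts
  an IOP and ocular geometry into in-wall hoop stress, and a Young's
  modulus range [E_min, E_max] turns that into the applied cyclic strain
  band [σ/E_max, σ/E_min].
* **Synthetic micrographs** — a seeded, ground-truthed generator of
  single-cell cytoskeleton images (elliptical cells with axial
  von Mises-oriented fibre texture) and nucleus images (heterochromatin
  foci over a uniform background), arranged in the experiment's
  3 loading groups × 3 timepoints design.
* **Morphometry** — maximum-intensity projection, mask areas in px²/µm²,
  and the width/length eccentricity ratio (1 = round, → 0 = elongated;
  note this is not the classical ellipse eccentricity).
* **Fibre anisotropy** — the FibrilTool-equivalent nematic-tensor score:
  per-pixel fibril directions (perpendicular to the intensity gradient)
  averaged as a unit-trace second-rank tensor, scored by the eigenvalue
  gap λ₁ − λ₂ ∈ [0, 1].
* **Chromatin condensation parameter (CCP)** — Sobel edge pixels divided
  by nuclear pixel area, with a relative edge threshold.
* **Statistics** — Anderson–Darling + Bartlett assumption gating into
  one-way ANOVA/Tukey HSD or Kruskal–Wallis/Dunn(Bonferroni), star codes,
  and box-whisker summaries.
* **Pipeline** — `run_pipeline()` wires simulate → project → measure →
  compare into one seeded, manifest-tracked run.

## Worked example

```r
library(scleromech)

## mechanics: healthy bovine IOP over the scleral modulus range
geom <- ocular_geometry(radius = 16.2e-3, wall_thickness = 1.6e-3)
reg  <- loading_regimen(mmhg_to_pascal(27), 1e6, 7e6)
band <- strain_band(reg, geom)
sprintf("stress %.0f Pa, band %.2f%%-%.1f%%", band$stress_pa,
        format_percent(band$strain_min), format_percent(band$strain_max))
#> "stress 18223 Pa, band 0.26%-1.8%"

## a strongly aligned synthetic cell, measured
cell <- render_cell(cell_phantom(semi_major = 45, semi_minor = 32,
  n_fibres = 60, orientation_kappa = 4, mean_orientation = pi/3,
  fibre_width = 2), seed = 1, canvas = c(128, 128))
fibre_anisotropy(cell$image, cell$mask)
#> Anisotropy 0.802, orientation 53.0 deg (4532 px)

## a condensed synthetic nucleus, measured
nuc <- render_nucleus(nucleus_phantom(semi_major = 26, semi_minor = 19,
  n_foci = 28, focus_radius = 3), seed = 1, canvas = c(96, 96))
ccp(nuc$image, nuc$mask)
#> CCP 0.3481 (543 edge px / 1560 nucleus px, threshold 0.15)
```

The anisotropy of 0.80 reflects the high orientation concentration
(κ = 4) of the generated fibres, and the recovered 53° orientation matches
the requested π/3 = 60° up to sampling noise. The CCP of 0.35 says about a
third of the (rim-excluded) nuclear area registers Sobel edges at the 0.15
relative threshold — a heavily condensed texture; an unloaded-like nucleus
with 8 foci scores around 0.19.

An end-to-end run with the default effect template (transient physiological
fibre alignment, delayed pathological alignment, strong but reverting
pathological chromatin condensation):

```r
run <- run_pipeline(study_config(), seed = 1, out_dir = "run_out")
run$comparisons   # one row per pairwise test per (metric, timepoint)
```

A thin CLI over the same functions lives at
`inst/scripts/scleromech-cli.R` (`strain`, `simulate`, `measure`, `stats`,
`run` subcommands).

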