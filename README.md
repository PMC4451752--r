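# endomosaic

Fully automatic quantification of corneal endothelium images from in
vivo confocal microscopy.

The corneal endothelium is a monolayer of roughly hexagonal cells on
the inner surface of the cornea. Its cell density is the main clinical
indicator of corneal health: below roughly 500 cells/mm² the
endothelial pump fails and the cornea decompensates, so density (and
secondarily cell size variability and shape regularity) is measured
routinely before and after eye surgery. Manual or semi-automatic
delineation of these images takes minutes per image; this package
automates the whole analysis.

## Methods at a glance

**Spectral density estimation.** The repetitive cell mosaic produces a
ring in the 2‑D frequency spectrum at the characteristic frequency
*f\** (px⁻¹); λ = 1/*f\** is the characteristic cell width. The mean
cell area follows as

    A = α / f*²,        δ = f*² / α   (cells per px², converted to mm⁻²)

where α is a dimensionless shape factor: 1 for a square lattice,
2/√3 ≈ 1.15 for a perfect hexagonal one, just below 1 for real
endothelium. Seven published estimators of *f\** are implemented
(`modeRM`, `1stRM`, `2ndRMAX`, `modePS`, `meanPS`, `medianPS`,
`modeRMrec`). The recommended `modeRMrec` is parameter-free: it removes
the central DC peak of the magnitude spectrum — together with its slow
tail, which can drown the ring — by dilation-by-reconstruction from the
DC sample, then takes the highest parabola-refined peak of the radial
mean.

**Stochastic watershed segmentation.** A seeded watershed is applied
*m* = 100 times to the inverted image, each repetition with fresh
uniform noise in [0, *u*] and a freshly rotated/translated hexagonal
seed grid whose density matches the spectral density estimate. The
per-pixel count of how often a pixel was a watershed line (the PDF) is
smoothed with a Gaussian of σ = *k*₍σ₎/*f\** , simplified with an
H-minima transform of depth *h* = *k*₍h₎·*m*/σ, and segmented by the
classical watershed. *f\** is re-estimated from the PDF itself before
smoothing (more robust than the image estimate), and a final seeded
watershed of the lightly smoothed original image re-aligns the
boundaries. Defaults *u* = 30, *k*₍σ₎ = 0.17, *k*₍h₎ = 0.002 are the
values found optimal by leave-one-out training on clinical images.

**Morphometry.** From the label image: cell density (inverse mean cell
area, mm⁻²), polymegathism (coefficient of variation of cell area, %),
and pleomorphism (percentage of cells with exactly six neighbors).
Border-touching cells are excluded from measurement but still count as
neighbors.

**Phantoms and evaluation.** `make_lattice()` builds the band-limited
square/hexagonal test patterns with known *f\** and α; `make_mosaic()`
builds realistic endothelium mosaics (jittered hexagonal Voronoi
tessellation, dark boundaries, noise, illumination gradient) with exact
ground truth: labels, one marker per complete cell, and an evaluation
polygon. `score_segmentation()` computes marker-based precision, recall
and F; `train_parameters()` grid-searches (*u*, *k*₍σ₎, *k*₍h₎) with
leave-one-out selection.

## Worked example

```r
library(endomosaic)

# a synthetic endothelium at 2000 cells/mm2, 0.557 um/px, with truth
ph <- make_mosaic(size_px = 500, density_mm2 = 2000, seed = 7)

estimate_f_star(ph$image, "modeRMrec")
#> <char_frequency> f* = 0.02602 px^-1 (bin 13 of N = 500), lambda = 38.43 px, method = modeRMrec

density_from_fstar(estimate_f_star(ph$image), alpha = 1)
#> <density_estimate> 2183 cells/mm2 (mean cell area 458.1 um2; f* = 0.02602 px^-1, alpha = 1.000)

seg <- segment_cells(ph, seed = 42)        # ~6 s: m = 100 repetitions
seg
#> <endo_segmentation> 500 x 500, 181 regions (f* = 0.02606 px^-1, 169 seeds/rep, m = 100)

measure_morphometry(seg, 0.557)
#> <morphometry_report> 128 cells: density 2165 /mm2, polymegathism 27.3 %, pleomorphism 40.6 %

score_segmentation(seg, ph$truth)
#> <seg_score> 122/125 regions correct of 122 true cells: p = 0.976, r = 1.000, F = 0.988
```

The spectral route reads the density directly off the ring (2183 mm⁻²
against a ground truth of 2036 mm⁻²; calibrating α on a phantom set
removes most of the remaining bias), while the segmentation route
measures every cell individually and additionally yields the size and
shape statistics. The F-measure of 0.988 says that essentially every
ground-truth cell was recovered one-to-one.

A command-line wrapper with the same functionality is installed at
`system.file("cli/endomosaic.R", package = "endomosaic")`, with
subcommands `phantom`, `fstar`, `density`, `segment`, `morpho`,
`score`, `run`.

## Vignette

`vignettes/endothelium-morphometry.Rmd` documents the model, every
tunable parameter with its default and rationale, the phantom
generator's scope and limitations, and the numerical design choices.
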