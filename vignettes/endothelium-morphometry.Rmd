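---
title: "Automated corneal endothelium morphometry: models, parameters, and design choices"
author: "endomosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated corneal endothelium morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the two quantification routes, every parameter that
matters, what the synthetic phantoms do and do not emulate, and the
numerical choices made where the underlying methods leave room.

## The imaging problem

In vivo confocal microscopy of the corneal endothelium shows a mosaic
of bright, roughly hexagonal cells separated by thin dark lines, often
with uneven illumination and substantial noise. The clinically relevant
quantities are the endothelial cell density δ (cells/mm²), the
polymegathism (coefficient of variation of cell area, %), and the
pleomorphism (fraction of six-sided cells, %). The package assumes
8-bit grayscale rasters cropped to the well-illuminated region, with a
known lateral sampling density (default 0.557 µm/px, the value for the
slit-scanning confocal instrument the defaults model).

## Route 1: spectral density estimation

A quasi-periodic mosaic of cell width λ concentrates spectral energy
on a ring of radius f\* = 1/λ in the 2-D frequency plane. The package
computes the FFT on the largest centered square crop (side N),
DC-centers the magnitude, and projects it onto radial bins
f ∈ {0, 1/N, …, 1/2} px⁻¹ by rounding each 2-D sample's radial
frequency to the nearest bin. Samples beyond 1/2 px⁻¹ (the frame
corners) necessarily round to the last bin; this keeps the projection a
partition of all N² samples and leaves the low-frequency bins, where
the ring lives, untouched. No windowing is applied before the
transform: the frame-edge leakage lands in the DC tail, which the
recommended estimator removes anyway.

Peaks of a radial profile are refined by a parabola through the three
samples around each local maximum (maxima defined by
`v[i] > v[i-1] && v[i] >= v[i+1]`, ties resolving toward lower
frequency, which is deterministic on plateaus); the refined position is
clamped to ±½ bin. Fits are done on linear profile values.

Seven estimators are provided. The mode-type ones (`modeRM`, `1stRM`,
`2ndRMAX`, `modePS`, `modeRMrec`) pick a peak; `meanPS`/`medianPS`
treat the radially averaged power spectrum as a distribution over
frequency bins and return its weighted mean/median — the
distributional reading is a design choice, since a "mean of a
function" that returns a frequency requires one. Their high-pass
filter zeroes the first `n_highpass` bins *including bin 0*; the DC
bin carries no frequency information, so excluding it from the
distribution is the only defensible option, and counting it in
`n_highpass` keeps the parameter equal to "number of bins removed".

`modeRMrec`, the recommended estimator, first subtracts from the
magnitude spectrum its dilation-by-reconstruction from the DC sample
(elementary 4-neighbor structuring element). The reconstruction equals
the central peak with its monotone tail; the difference contains the
ring alone. This is a high-pass filter tailored to the image at hand
with no parameter. Two numerical notes: the reconstruction is computed
with the standard two-sweep + FIFO-queue hybrid algorithm, which is
exactly (bit-for-bit) the fixed point of the iterative definition; and
while the reconstructed tail is non-increasing along rays from DC in
the continuous idealization, on a discrete grid off-axis paths can
carry values past a spectral "moat", producing small (few percent)
local increases — the tests assert ray monotonicity only up to that
slack.

Density follows from the shape factor α via A = α/f\*², δ = f\*²/α.
α is 1 for a square lattice and 2/√3 ≈ 1.155 for a perfect hexagonal
one — the densest packing, so real mosaics satisfy α < 1.155, and
irregular ones drift below 1. With no calibration data the package
defaults to α = 1. `calibrate_alpha()` implements leave-one-out
calibration: per training image α\_j = f\*\_j²/δ\_j (δ\_j from the
ground truth, n\_eval/A\_eval), and each image receives the arithmetic
mean of the *other* images' values. The arithmetic mean was chosen as
the simplest unbiased aggregate; a regression of δ against f\*²
through the origin would weight dense images more and is noted here as
the plausible alternative.

## Route 2: stochastic watershed segmentation

The watershed of the inverted image segments it into one region per
local minimum, with lines along the bright cell boundaries; noise makes
raw minima hopeless, so the package uses the stochastic watershed:

1. **Seed count.** n\_seeds = A\_I·f\*²/α, the image area times the
   spectral density estimate, with α = 1 at this stage (the algorithm
   is deliberately insensitive to the seed count, so the shape
   correction is not needed here).
2. **Seed placement.** A hexagonal grid with one seed per hexagon of
   edge t = √(2/(3√3)·A\_I/n\_seeds) — equivalently a triangular
   lattice with spacing √3·t — given a rotation uniform in [0, 2π) and
   a translation uniform over one grid cell. This reading of the grid
   construction is the only one for which the seed density equals the
   requested cell density, which is the construction's stated purpose;
   a honeycomb-vertex reading would double it.
3. **PDF.** m repetitions: add uniform noise in [0, u] to the inverted
   image (promoted to floating point, no clipping — clipping at 255
   would bias the bright ridges), place a fresh random grid, run the
   seeded watershed, and increment a counter at every watershed-line
   pixel. Counts lie in [0, m] and estimate each pixel's probability of
   being a cell boundary.
4. **Extraction.** Smooth the counts with a Gaussian of
   σ\_PDF = k\_σ/f\*; suppress minima shallower than
   h = k\_h·m/σ\_PDF with the H-minima transform (erosion
   reconstruction, computed through its dual); flood the result from
   its regional minima (classical watershed). h acts as an absolute
   depth on the smoothed float counts — the m/σ scaling already
   normalizes it, so no renormalization of the counts is performed.
5. **f\* re-estimation.** The PDF is a clean rendition of the mosaic
   (no illumination field, no texture), so `modeRMrec` on the counts
   usually beats the image estimate; its result sets σ\_PDF. If no
   ring is found in the PDF the initial estimate is kept, with a
   message.
6. **Border re-alignment.** The smoothing displaces boundaries, so
   every region is shrunk by 20 % — keeping pixels with
   D\_c/(D\_c + D\_b) < 0.8, with D\_c the Euclidean distance to the
   region's center of mass and D\_b to its boundary (watershed lines
   and the image edge; the frame is padded as background before the
   distance transform). The shrunken regions seed a final watershed of
   the original inverted image smoothed with σ = 2. The
   distance-ratio definition is used verbatim rather than an erosion,
   because it is scale-free per region. A centroid falling outside a
   non-convex region is replaced by the region pixel nearest it; a
   region whose marker would be empty keeps its full extent as seed,
   so the region count is always preserved.

All watersheds are Meyer floods with 4-connected regions, watershed
lines where floods meet, and first-in-first-out tie-breaking on equal
priority, so every run is a deterministic function of its master seed.
The master seed spawns one sub-seed per repetition (noise and grid
placement together), making repetitions independent but the whole run
reproducible.

### Parameters

| parameter | meaning | unit | default | rationale |
|---|---|---|---|---|
| u | per-repetition noise range | gray levels | 30 | optimal in leave-one-out training on clinical images |
| k\_σ | PDF smoothing relative to cell size (σ\_PDF = k\_σ/f\*) | — | 0.17 | same training |
| k\_h | minima suppression (h = k\_h·m/σ\_PDF) | — | 0.002 | same training; near-optimal even at 0 |
| m | repetitions | — | 100 | variance/time compromise; mean F is flat in m |
| α | shape factor | — | 1 | implicit assumption of prior work; calibrated values fall just below 1 |
| sampling | lateral sampling density | µm/px | 0.557 | the modeled instrument |

## Evaluation and training

Ground truth per image is one marker near the middle of each complete
cell inside a hand-drawn evaluation polygon. A segmented region is
*considered* if it overlaps the polygon by at least a quarter of the
average region size, the average being taken over the regions that
intersect the polygon (a local scale; the plausible alternative —
averaging over all regions in the image — differs only through cells
far outside the polygon). A considered region is *correct* if it
contains exactly one marker and ≥ 85 % of its pixel area lies inside
the polygon. Precision = correct/considered, recall = correct/n\_eval,
F = their harmonic mean. Pixel membership in the polygon uses the
even-odd rule at pixel centers; areas are pixel counts.

`train_parameters()` scores every image under every (u, k\_σ, k\_h)
triple — seeding during training from the ground truth,
n\_seeds = A\_I·n\_eval/A\_eval, so that the spectral estimate does not
influence the training — and selects, per image, the triple with the
best mean F over the *other* images. Each (image, triple) pair is
segmented once with a deterministic derived seed: training does not
average repeated stochastic runs, which keeps it reproducible and
affordable; the stochasticity experiment below justifies this (the
run-to-run IQR of F is an order of magnitude below the differences the
trainer must resolve).

## Morphometry

Cell area is the label support (boundary pixels excluded), converted to
µm² by the squared sampling density; density = 10⁶/mean area;
polymegathism = population standard deviation over mean (a
definitional choice, fixed and documented — sample sd would differ by
< 1 % at typical cell counts); pleomorphism = percentage of cells with
exactly six neighbors. Border-touching regions are discarded from
measurement but retained as neighbors: they bound the measured cells
even if they cannot themselves be measured. Two regions are neighbors
iff they touch a common boundary pixel, where "touch" reaches through
the boundary line (two 8-connected steps), making the relation robust
to boundary lines up to about 3 px wide. No stereological counting
frame is applied; discarding border cells therefore biases the density
slightly upward (large cells are more likely to touch the border), a
bias shared by the standard clinical practice this mirrors.

## The phantom generator

`make_lattice()` renders the two classic band-limited test patterns:
square or flat-topped hexagonal cells of side-to-side length s, as
bright cells with 1-px dark lines, low-pass filtered to
3·f\* (the acceptance-relevant content is the fundamental ring, so the
cutoff shape is immaterial), with a lattice site at the image corner.
True values: f\* = 1/s, α = 1 (square); f\* = 2/(√3·s), α = 2/√3
(hexagonal).

`make_mosaic()` emulates a clinical image: a Voronoi tessellation of a
jittered hexagonal point process, bright cells (mean 190, per-cell
spread 4 gray levels), dark boundary lines (60) of width 2 px
(pixels within half a width of a Voronoi edge, measured exactly from
the generating geometry), a multiplicative linear illumination gradient
(±15 %), and additive Gaussian noise (sd 8). Defaults: 500×500 px at
2000 cells/mm² and 0.557 µm/px, about 155 cells per frame — a typical
post-keratoplasty density at the modeled instrument's field of view.
The jitter→size-CV mapping was calibrated once by simulation (3 seeds ×
10 jitter levels on 600-px mosaics) and frozen as a monotone lookup
table; the default size CV of 0.25 matches healthy-range polymegathism.
The per-cell intensity spread was fixed at 4 gray levels when the
defaults were frozen: real slit-scanning images show fairly uniform
cell brightness, and a strong flat per-cell variation would inject
unrealistic low-frequency spectral energy. The unjittered lattice is
given a fixed fractional phase offset so that no Voronoi edge
coincides exactly with the frame border — a measure-zero alignment no
tissue exhibits, which would otherwise create zero-area sliver cells.

Ground truth is exact by construction: the label image (boundary
pixels 0), one marker per complete cell (the interior pixel nearest the
cell centroid), and an evaluation polygon traced around the union of
the complete cells, mirroring the expert protocol of marking cells and
outlining the marked set.

**What the phantoms do not emulate** — and hence what passing tests do
not show about clinical data: guttae and other pathology, anisotropic
blur and motion artifacts, realistic intracellular texture, and
gray-level histograms of real instruments. The texture gap matters in
one identified place: with several seeds per cell, intra-cell watershed
lines on texture-free cells follow the static image noise and the
seed-grid geometry more coherently than they would on textured clinical
cells, which makes the PDF's spurious seed-scale ring stronger on
phantoms (see Limitations).

## Experiment sizes

The robustness experiments in the test suite run on five default
mosaics (≈150 cells each): mean F across seed counts of 0.5×/1×/2× the
optimum (spread < 0.05); frequency corruption by 2× with and without
PDF re-estimation; 12-run stochasticity at m = 100 and m = 25 (IQR of
F ≤ 0.08, mean difference < 0.02); and a 3-image, 6-triple trainer run
with one clearly optimal planted triple. These sizes resolve the
effects of interest well above the run-to-run noise while keeping the
whole suite at desk scale.

## Known limitations

- **Incomplete rescue at extreme frequency corruption.** Re-estimating
  f\* from the PDF fully absorbs moderate errors in the initial
  estimate (at √2× corruption the result is within ~0.01 F of a
  correctly-smoothed run at the same seed count). At 2× corruption the
  seed count is 4× too high, and on a minority of phantoms the PDF
  re-estimate locks onto the seed-lattice ring at twice the cell
  frequency, leaving the result degraded. The texture-free phantom
  cells exaggerate this failure mode relative to clinical images, but
  it is intrinsic to mode-picking on a contaminated PDF.
- **Boundary-exclusion density bias.** Defining cell area as the label
  support excludes the watershed lines, overstating density by roughly
  the line-width-to-cell-width ratio (a few percent at default
  conditions, more for very small cells). The bias is uniform across
  methods compared this way.
- **Directionally biased mosaics.** Strongly elongated cell patterns
  produce an elliptic spectral ring; the radial projection widens and
  the mode approximates the mean ring radius. No elliptic fit is
  attempted.
- **meanPS/medianPS sensitivity.** Their high-pass bin count must be
  tuned to the imaging setup; they are included for comparison, not
  recommendation.
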