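---
title: "Monitoring microtissue cultures in square-microwell arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring microtissue cultures in square-microwell arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microwellr)
```

## The monitoring problem

Microtissues (spheroids) self-assemble from a few hundred cells in
non-adherent square-microwell inserts: the A400 platform moulds 1200
microwells of 400 um pitch per culture well (about 250 cells per
microtissue when 300 000 cells are seeded), the A800 platform 300
microwells of 800 um pitch (about 1000 cells). During weeks of
differentiation the medium is half-exchanged repeatedly (days 3, 7, 10, 14
and 17 by default), and every liquid-handling event risks flushing
microtissues out of their microwells. Escaped microtissues fuse into
irregular agglomerates and the affected microwells stay empty, so the
percentage of empty microwells is a natural, noninvasively imageable
quality attribute of the culture — alongside per-microtissue morphometrics
(area, diameter, eccentricity) and volume statistics.

Brightfield images of microwell plates are hard to segment directly: the
moulded well walls produce a strong dark grid that dominates simple
thresholding. The pipeline implemented here therefore follows the
established two-stage pattern: supervised *pixel classification* turns the
raw image into class probability maps, and classical *object
identification* turns the probability maps into measured objects.

## Pipeline stages and their parameters

### Pixel classification

Two independent random-forest classifiers (default 100 trees each) are
trained on sparse pixel labels, one for microtissue-vs-background and one
for microwell-boundary-vs-background. Both work on the same multi-scale
filter bank: six feature families (Gaussian, gradient magnitude, Laplacian,
difference of Gaussians, largest-magnitude Hessian eigenvalue, largest
structure-tensor eigenvalue) at five scales (0.7, 1.0, 1.6, 3.5, 5.0 px),
30 planes in total. The scale set was chosen once to span sub-pixel texture
up to object-scale structure at the working resolutions of 2–8 um/px; it is
configurable through `filter_bank_spec()`. Convolutions are separable with
reflected borders, so feature planes are translation-equivariant away from
the image edge. The sampled second-derivative kernels have their DC
component removed, making derivative features of a constant image exactly
zero.

Sparse labelling mimics interactive annotation: the well array is split
into four quadrants and a handful of microwell blocks per quadrant (six by
default) contribute capped numbers of foreground and background pixels
(`sparse_labels_from_truth()` generates such label masks from synthetic
ground truth). No class reweighting is applied — the labelled sets are
taken as given, matching the interactive-labelling paradigm.

Probability maps over multi-megapixel well images are produced by a
compiled traversal of the fitted forest that returns exactly the vote
fractions of `predict(..., type = "prob")`; the test suite asserts the
equivalence.

### Object identification

The tissue probability map is thresholded globally by Otsu's criterion on a
256-bin histogram (pixels at or above the threshold are foreground; a
constant map is a degenerate-input error). Touching objects are split by a
distance-transform watershed: the Euclidean distance map is smoothed with
`sigma_d = 2` px and flooded with a seed-merging radius of half the
expected object diameter (`d_min`). Ridge pixels are assigned by the
watershed's deterministic flooding order. Objects are then filtered by
equivalent diameter (default 0.25–1.2 times the platform's expected
microtissue diameter), eccentricity (max 0.95), compactness (max 2) and
area (implied by the diameter bounds); every bound is overridable through
`filter_criteria()`.

Morphometrics use the pixel-count area, unweighted centroid, moments-based
eccentricity and a perimeter traced along the outer contour polygon. Traced
perimeters of digitized discs overshoot the true circumference by about 5%,
which is why the form-factor invariant carries a 5% discretization
tolerance; the perimeter is floored at the equivalent-circle circumference
so that compactness never drops below 1 for few-pixel objects.

### Microwell grid and occupancy

The boundary probability map is thresholded (Otsu), small gaps in the grid
lines are closed morphologically (disc radius equal to the boundary-line
width), and interior connected components of plausible area
(0.4–1.3 pitch²) whose bounding box fits a grid cell become microwell
candidates. Candidates are snapped onto the ideal square lattice fitted to
their centroids by least squares; snapping makes the microwell count robust
to locally broken boundary pixels and can be disabled. A microwell is
called empty iff no microtissue centroid lies within its boundary polygon;
a centroid exactly on the polygon edge counts as inside (the inclusive
reading — ties are rare but a convention is required). A centroid inside
two polygons raises an error rather than picking silently, since it signals
a grid-extraction failure. Wells holding several microtissues are recorded
as "multi" but count as filled in the percentage summaries.

### Particle statistics

Assuming spherical shape, each projected area A (mm²) maps to a volume
(4/3)·pi·(A/pi)^{3/2}. Per (platform, day) dataset the volumes are sorted,
a cumulative weight curve is built (volume-weighted by default — the usual
Dv convention; number weighting by flag) and D10/D50/D90 are read off with
linear interpolation at type-7-style plotting positions
u_i = (C_i − w_i)/(C_n − w_n); for equal weights this reduces to
`stats::quantile(type = 7)`, which the tests use as an independent oracle.
The span (D90 − D10)/D50 summarizes distribution width, and the per-well
yield is `microwells_per_well × mean volume × (100 − pct_empty)/100`.
The published summary table bundled as `platform_summary_reference()`
is reproduced by these formulas from its own printed columns to within
printing precision (about 1% for span, 0.5% for the predicted volumes).

### Design-of-experiments analysis

Liquid-handling optimization uses full factorial designs: aspiration ×
dispension (optionally × needle depth), replicated wells, observed at each
timepoint. The published second design crossed 4 aspiration levels (up to
500 uL/s, about five times manual speed) with 2 dispension levels; those
level sets are the defaults of `build_design()` but are plain
configuration. The response model is
`pct_empty ~ aspiration * dispension + time` with all factors categorical
(matching the "factor levels" framing and main-effects plots), fitted by
`stats::aov` with sequential sums of squares — on balanced designs these
equal the marginal sums, and unbalanced inputs trigger a warning. The
response is the raw per-well empty percentage; no transformation is
applied since results are reported on the percentage scale. Significance
uses alpha = 0.05 with conventional star codes. Well-position effects
(spatial clustering of displacement in the lower plate half has been
observed in practice) are deliberately not modelled.

## The synthetic plate generator

No public image data accompany this problem, so every stage is validated
against a generator that renders the relevant image structure: a bright
background (0.82), darker textured elliptical microtissues (0.45), the
darkest boundary grid (0.15) on a 0–1 intensity scale, a linear horizontal
illumination ramp (±4%) and additive Gaussian noise (SD 0.02). This is the
simplest model that makes Otsu separation nontrivial and forces the
classifier to use texture and multi-scale context, not a single global
threshold.

Geometry follows the platform presets: rectangular arrays (30 × 40 for
A400, 15 × 20 for A800) so that exactly the nominal number of lattice
sites lies inside the well footprint; 8 um/px for full-well overviews and
2 um/px for 1600 um × 1600 um field-of-view tiles. Mean equivalent
diameters default to 150 um (A400) and 250 um (A800), consistent with
published mean volumes per microtissue of 0.0015–0.009 mm³; the
per-well diameter CV defaults to 0.10 with draws truncated at ±2 SD,
reflecting the narrow within-well size spread of microwell self-assembly
(the much wider published spans arise from pooling wells and days).
Eccentricities are uniform on [0, 0.6]. Escaped microtissues are placed on
grid-line intersections with jitter, never overlapping housed objects, so
their centroids fall between microwells.

Each render returns pixel-exact ground truth (tissue mask, boundary mask,
per-microwell occupancy, object catalog) and is bit-reproducible from its
seed; the random draw order is documented so tests can replay individual
sampling steps. Longitudinal series apply a per-media-change escape
probability `base_escape_prob × (1 + a·aspiration) × (1 + d·dispension)`
(clamped to [0, 1]) to each still-housed object; escape is irreversible, so
empty counts are non-decreasing in time. The coefficients are free
parameters — no published per-media-change escape probabilities exist to
calibrate them — and the form is intentionally the simplest one that makes
empty-well percentages increase with time and respond monotonically to
speeds.

What the generator does *not* emulate: point-spread blur and vignetting
beyond the linear ramp, refraction artefacts of the moulded well walls,
debris, uneven focus, fusion of touching microtissues, and multi-channel or
z-stack imaging. Passing the synthetic gates therefore demonstrates that
the algorithms are correct and well-calibrated on images with the right
coarse structure; it does not certify performance on any particular
microscope's real images, for which classifiers must be retrained on
real annotations.

## Numerical and design choices

- Pixel coordinates are 0-based (x = column, y = row), origin top-left;
  physical coordinates are pixel × pixel_size (um). All polygons are pixel
  coordinates.
- Otsu uses 256 histogram bins on the [0, 1] probability range; the
  threshold is inclusive (`>=`).
- The watershed seed radius is `d_min/2` with `d_min` half the expected
  diameter; `sigma_d = 2` px smooths the distance map so elongated objects
  do not oversplit.
- Percentile interpolation is linear between adjacent cumulative points;
  a single volume returns itself for every cutoff.
- Degenerate inputs fail loudly: constant probability maps, single-class
  training labels, saturated ANOVA models, constant responses, unsorted
  timepoints and inverted filter bounds all raise errors instead of
  returning silently wrong numbers.
- Reported CSV floats are fixed at six significant digits so repeated runs
  are byte-identical.

## Validation gates and problem sizes

The shipped test suite regenerates everything from seeds and checks, among
~500 assertions: bit-reproducibility of renders; occupancy conservation;
replay of the generator's Bernoulli draws; closed-form checks of disc and
ellipse morphometrics; watershed splits within 2 px of the analytic
bisector of two overlapping discs; Otsu's Dice within 0.05 of the
exhaustive best threshold; occupancy assignment equal to brute-force
point-in-polygon; D-values equal to brute-force cumulative scans; ANOVA
sums of squares equal to hand arithmetic, with type-I error in [0.03, 0.07]
per term over 1000 null simulations and >= 90% power for a 2-SD-per-step
time effect.

The end-to-end gates run at desk scale: 5 training + 5 validation
field-of-view tiles per platform at 2 um/px for the segmentation gate
(mean held-out Dice >= 0.836), and 10 full wells (mixed platforms, empty
fractions 5–30%, escaped objects present) at 8 um/px for the occupancy gate
(per-microwell accuracy >= 94%), with classifiers trained on one seeded
well per platform. Grid extraction must return exactly 1200 (A400) and 300
(A800) microwells from clean renders. `scripts/acceptance.R` recomputes all
of these from scratch for any seed.

## Known limitations

- The pipeline assumes pixel-exact registration between the tissue and
  boundary probability maps (same source image); no registration step is
  provided.
- Square lattices only; hexagonal or circular microwell geometries and
  stitched tile mosaics are out of scope.
- Object identity is not tracked across timepoints, and fusion kinetics
  are not analysed.
- The displacement model is phenomenological; its coefficients are not
  calibrated against measured per-media-change escape rates.
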