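---
title: "celltyper: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celltyper: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind each
pipeline stage, the conventions and tunable parameters, the design choices
made where several definitions were defensible, and what the synthetic
validation does and does not demonstrate about real data.

## The pipeline model

`celltyper` assumes 2D single-plane images with up to three channels. One
channel — Marker I, typically a nuclear or cytoplasmic stain — carries the
*detection* signal: a cell is a connected bright region on Marker I. The
remaining channels (Markers II/III) carry *phenotype* signal and are only
ever measured inside regions detected on Marker I. This separation is the
core modelling assumption: it makes classification rules interpretable
("mean Marker II intensity above its Marker I counterpart, at least eight
foci") but also means the pipeline cannot detect cells visible only in a
secondary channel.

All coordinates use x = column, y = row, 0-based, origin top-left; every
output table repeats this in a header comment. When a region of interest is
set, analysis happens on the crop but all reported coordinates are mapped
back to original-image coordinates by adding the crop offset.

## Thresholding

Detection starts from a 256-bin histogram of the (optionally preprocessed)
Marker I plane. 16-bit planes keep full depth for measurements but are
binned as `round_half_up(v * 255 / 65535)` for thresholding — the classical
algorithms are defined on 8-bit histograms — and the chosen level is mapped
back to the native scale before binarization (`foreground = value > t`).
The binning convention for 16-bit data is a documented package choice; no
claim of bit-exact parity with any other tool is made.

Sixteen classical global methods are implemented from their published
definitions: iterative intermeans ("Default", the original ImageJ-style
IsoData variant, and "IsoData", the Ridler–Calvard iteration with integer
class means), Otsu's between-class variance (exhaustive search, first
maximum), Huang's fuzzy-membership entropy, Li's iterative minimum cross
entropy, Kapur's maximum entropy plus its Rényi-entropy generalization
(α = 0.5, 1, 2 combined with the standard β-weight rule), Yen's maximum
correlation, Shanbhag's information measure, Kittler–Illingworth minimum
error (iterated from the histogram mean; if the discriminant turns negative
the current level is returned), Tsai's moment preservation, the 50th
percentile, the mean, Triangle (signed sag below the chord from the longer
tail's end to the peak; the tail is mirrored so the search always runs
tail-to-peak), and the smoothing-based Intermodes and Minimum (3-bin running
mean until exactly two maxima; they fail with a clear error on histograms
that never become bimodal, as does any method on a constant image).

Ties in criterion maximization are always resolved toward the lower level
(first maximum), making every method deterministic for a given histogram.
The test suite checks all sixteen against independently coded, loop-style
reference transcriptions on randomized bimodal histograms.

## Segmentation conventions

* Connectivity: 8-connected foreground, 4-connected background — the
  standard duality of particle analysis. Two cells touching only at a pixel
  corner are one component.
* Cell IDs: 1..N in raster order (topmost, then leftmost first pixel). The
  underlying ordering of labels is otherwise arbitrary, so the package fixes
  it for reproducibility.
* Watershed: the binary distance-transform variant. Seeds are local maxima
  of the Euclidean distance map; peaks whose height above a connecting
  saddle is below 0.5 px are merged (this suppresses spurious splits from
  rasterization); the watershed lines are removed from the foreground as
  1-pixel separations, thinned toward the higher-label side. Component
  counts can only grow.
* Hole filling (off by default): background components not 4-connected to
  the border become foreground.
* Contours: each cell's outer boundary is traced as a *crack* polygon over
  pixel corners, so the polygon's shoelace area equals the pixel count
  exactly for simply-connected regions (fill holes first if regions may
  contain holes). At diagonal contacts the tracer prefers the turn away
  from the region, keeping 8-connected pixels on a single loop.

## Feature definitions

Shape features are computed from the pixel set and crack contour:

* `perimeter`: crack length minus `(2 − √2)/2` per direction change. This
  corner correction makes a 45° staircase measure √2 per diagonal step and
  leaves axis-aligned runs exact; a digitized disk of radius 20 px then has
  circularity ≈ 0.90. Results are bit-reproducible within this package;
  exact parity with other tools' perimeters is not claimed.
* `circularity = 4πA/P²` (clamped to 1), computed in pixel units so it is
  calibration-invariant.
* Ellipse axes from second central moments with the per-pixel 1/12
  unit-square term (so a 1-px-wide bar has a finite minor axis); full axes
  are `4√λ`. `roundness = 4A/(π·major²)`, `aspect_ratio = major/minor`.
* `solidity` = pixel count / area of the convex hull **of pixel corners** —
  taking corners (not centres) guarantees solidity ≤ 1. Feret diameters come
  from rotating calipers on the same hull.
* Calibration: areas scale by `pixel_width · pixel_height`, lengths by
  `pixel_width`; centroids and bounding boxes stay in pixel coordinates.

Intensity statistics are always measured on the **raw** planes — the
preprocessing chain feeds segmentation only, so measured intensities remain
comparable across runs with different preprocessing. Conventions: population
standard deviation, population skewness, excess kurtosis (both 0 for
zero-variance regions), mode = lowest of tied most-frequent values,
`raw_integrated_density = Σ values`, `integrated_density = mean × calibrated
area`. Population summaries use sample variance (n − 1) and type-7
(linearly interpolated) quantiles — the same quantile convention used for
the quartile-based classification bounds.

## Secondary markers and foci

Measurements on Markers II/III run on the Marker I regions, optionally
eroded or dilated with a disk (radius ≥ 1 px). Erosion can empty a small
region; such cells get missing values rather than zeros. Dilation never
annexes a neighbouring cell's original pixels, and pixels contested by
several dilated cells go to the nearest original region (ties to the lower
ID) — the underlying tool this workflow emulates does not specify collision
behaviour, so the package fixes a deterministic rule.

Foci counting implements the "Tolerance" parameter (default 30) with
intensity semantics: a local maximum (plateaus count once, at their
centroid) is accepted iff

1. it cannot be reached from any higher point without descending at least
   `tolerance` grey levels (flood-fill prominence; equal-valued peaks
   connected above `v − tolerance` merge into the first in raster order),
   and
2. its value is at least `tolerance` above the median intensity of the cell
   region — the "local threshold" role of the parameter.

Condition (2) is a deliberate design decision: prominence alone always
accepts a region's global maximum, so a spot-free but noisy nucleus would
count one focus. Referencing the region median keeps spotless nuclei at
zero while leaving genuine spots (amplitudes well above tolerance)
untouched; both conditions get stricter as tolerance grows, so counts are
monotone non-increasing in tolerance. An alternative reading of the
parameter — a minimum *distance* between accepted maxima — was considered
and not implemented; the default value (30 grey levels) and the "local
threshold" description both fit intensity semantics, and distance
suppression would not be monotone in the same sense. Foci are searched on
the raw plane by default; an optional Gaussian pre-smoothing sigma is
exposed in the configuration for noisy material.

## Classification semantics

* Relevance filters: inclusive intervals on Marker I features, conjunctive.
  Only relevant cells are classified; the rest are `excluded`.
* Cell types: ordered conjunctions of constraints. All interval bounds are
  inclusive; comparisons support `<, ≤, >, ≥`. A cell receives the *first*
  matching type — the underlying rule language allows overlapping
  definitions without specifying a resolution, so the package keeps the
  output single-valued by definition order and reports every match in a
  diagnostic `all_matching_types` column.
* Quartile bounds (`"Q1"/"Q2"/"Q3"`) resolve per analysis over the relevant
  cells, so batch runs adapt them per image. "In the Q4 quartile" is
  `value ≥ Q3`, "in Q1" is `value ≤ Q1`; with types ordered so the extreme
  rules come first, the inclusive interquartile rule `Q1 ≤ v ≤ Q3` cleanly
  captures the middle.
* Quadrant analysis: "high" on an axis means `value ≥ threshold`; the four
  counts always partition the relevant cells with both features present.
* Curve fits: linear/polynomial by ordinary least squares; power,
  logarithmic and exponential by log-linearization (the documented
  estimator), with R² always computed on the original scale. Domain
  violations (non-positive x or y where logs are taken) are errors naming
  the offending points.

## Configuration and batch processing

The XML configuration captures every pipeline choice (schema version 1.0,
defined by this package; it is strict — unknown elements or attributes are
rejected with their location, and cross-field consistency such as
"constraints may only reference mapped markers" is validated before any
image is processed). Numbers are serialized with 17 significant digits so
save→load is a lossless round-trip.

Batch mode processes a directory in lexicographic filename order, writes one
folder per image (identical to the single-image run) plus a `summary`
folder, logs and skips failing images, and records them in the summary
table. CSV values are printed at 6 significant digits with fixed formatting,
making repeated runs byte-identical.

## The synthetic generator

The generator renders elliptical cells on a constant background with
per-cell intensities, optional planted Gaussian foci, additive Gaussian
noise clipped to the bit range, and records exhaustive ground truth (pixel
sets, intensities, foci coordinates, intended classes). Placement is
rejection sampling with a minimum bounding-circle separation; an
`overlap_fraction` deliberately fuses pairs at 75 % of the sum of their
radii to exercise watershed. All randomness flows from one seed.

Preset conditions (the defaults *are* the study conditions the validation
uses):

* `nuclei` — disks of radius 8–16 px at intensity 180–220 over background
  10, noise sd 3: comfortable SNR for the count/area-recovery checks.
* `foci` — nuclei at constant Marker I value 100; Marker II base either 40
  or 160 (equal probability) plus 0–12 spots of amplitude 100 (≥ 3× the
  default tolerance), σ = 1.2 px, centre separation ≥ 5 px, noise sd 2. The
  intended "positive" label (high base and ≥ 8 foci) is thus decidable from
  the generator's own bookkeeping with wide margins on both conditions.
* `spirochete` — a noiseless monochrome scene with five morphology classes
  in proportions BC/R/E/S/N = 0.10/0.15/0.15/0.25/0.35 and geometry chosen
  so class areas and circularities are strictly ordered (small and normal
  bacteria are mildly elongated ellipses, aspect 2.2–2.8, so their digital
  circularity stays clearly below that of round cells). With `n_cells`
  divisible by 4 the per-image quartiles fall exactly between classes and
  the quartile recipes (BC by area ≥ 500 px; R = circularity in Q4; E/S/N
  by area quartiles) reproduce the intended partition exactly.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate: realistic point-spread functions, shot noise, uneven
illumination, intensity gradients within cells, densely overlapping tissue,
or any staining biology. The synthetic checks validate the *computational*
contracts (recovery of planted truth under controlled conditions); they are
not evidence about segmentation quality on difficult real material.

## Problem sizes and numerical notes

The shipped test suite and the acceptance script size their simulations for
a desk-scale run: 50 random histograms across all 16 threshold methods, 20
random scenes for the segmentation/feature invariants, 100 nuclei for
foci-count recovery, 200 randomized tables for classifier equivalence
against a brute-force evaluator, 100 random configurations for XML
round-trips, and 3-image batches for determinism checks. Degenerate inputs
are errors, not silent defaults: constant images cannot be thresholded,
empty regions have no features, quartile bounds need at least four relevant
cells, and infeasible packings abort scene generation after bounded
retries.

## Known limitations

Global thresholding only (no local/adaptive methods, no learned
segmentation); single-plane 2D analysis; at most three channels; CSV as the
only tabular output; the XML schema is this package's own. Perimeter (and
hence circularity) follows the documented corner-corrected crack convention,
which tracks but does not exactly match other tools' perimeter estimators.
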