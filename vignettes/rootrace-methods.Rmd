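---
title: "Tracing seedling root systems from labelled plate images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing seedling root systems from labelled plate images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootrace)
```

# The problem

Seedlings grown on germination paper in upright petri dishes expose their
whole root system to a camera: a cheap assay that scales to hundreds of
genotypes, provided the image analysis keeps up.  Each photograph contains a
barcode label on the dish lid (species, mapping population, genotype,
replicate number), a square of blue germination paper (99 mm x 99 mm),
typically three seeds, and one to seven roots per seed.  `rootrace`
implements the full computational pipeline around such images:

1. **ingest** — locate and decode the label, crop the growth zone, calibrate
   the mm-per-pixel scale, and file images into a
   `species/population/genotype/replicate` folder database;
2. **markers** — refine operator-placed seed and root-tip pixel markers;
3. **tracing** — recover each root as a minimal-cost path on a Dijkstra
   cost map and associate every tip with its seed;
4. **traits** — per-seed root architectural parameters and per-genotype
   summaries;
5. **qc** — an error typology scored against ground truth, outlier flags,
   and a fully automatic segmentation baseline;
6. **synthetic plates** — a generator producing images *with exact ground
   truth*, so that every stage above is testable without any real data.

Coordinates throughout are 1-based `(row, col)` with row increasing
downward (the gravity direction for an upright dish); rectangles are
inclusive on both ends.

# Ingestion

## Label location

The locator exploits two properties of the label region: it is bright, and
— because the barcode modules are smaller than the filter window — it is
*uniformly heterogeneous*.  The steps are: grayscale conversion (standard
luma weights); a local variance filter (default window 15 px, which must
exceed the module pitch); normalisation of the variance image to the
grayscale's own range, so the two are commensurable and the whole construct
scales with image brightness; the pixel-wise minimum of the two images,
which is bright only where the image is both bright and locally
heterogeneous; a relative threshold at 80% of the maximum of that minimum
image; and the bounding box of the largest connected component.  Because
every step is relative, the locator is invariant to uniform brightness
scaling up to saturation.

The located box tends to cover the symbol's bright backbone rather than the
whole label, so the decoder works on a generously expanded window and grows
it further if decoding fails — the decoder re-locates the label inside its
window, so an over-large window costs nothing.

## The barcode symbology

No QR library is part of this package's dependency set, so `rootrace`
carries its own compact 2-D matrix symbology (it is *not* ISO/IEC 18004):
a square module grid in one of the sizes 21, 25, ..., 57; three QR-style
7x7 finder patterns in the top-left, top-right and bottom-left corners,
each separated from the data by a one-module white separator; a quiet zone
of at least 4 modules; and a byte stream of `[length | payload | CRC-32]`
laid row-major over the data modules, MSB first, with a checkerboard fill
on unused modules (which keeps the region heterogeneous for the locator).
The payload grammar is `species|population|genotype|replicate`.  Decoding
estimates the module pitch from the 7-module top edge of the top-left
finder, snaps the grid size to the nearest legal size, samples a 3x3
median at each module centre, verifies the finder cores and separators, and
rejects any symbol whose CRC-32 does not match.  The CRC makes a wrong
decode (as opposed to a failed one) vanishingly unlikely.

## Growth-zone crop and calibration

The growth zone is segmented on the hue channel: the blue paper sits near
hue 220 degrees, far from both the warm background and the neutral label, and
far from the 0/360 wraparound (a red-dominant paper would need a hue
rotation upstream).  Otsu's threshold splits the hue histogram, the largest
connected component is kept, its holes filled, the exterior blacked out and
the image cropped to the component's bounding box.  The scale is calibrated
as `paper_width_mm / paper_width_px` with a default paper width of 99 mm.

# Marker refinement

Operators place one marker per seed and per visible root tip.  Markers are
refined in three steps.  First the working grayscale `I` (roots bright) is
multiplied by a sum of isotropic 2-D Gaussians centred on the marker
positions,

$$J(x) = I(x)\sum_i N(x - x_i, \sigma^2),$$

which suppresses everything far from the markers.  The Gaussians are used
with peak value 1 rather than unit mass: only the argmax structure of `J`
matters, so the normalisation constant is irrelevant.  Second, the strict
3x3 local maxima of `J` within a search radius (default `3 * sigma`,
beyond which the kernel is negligible) become candidate positions; a
prominence floor (default 5% of the window maximum) suppresses noise bumps
— the floor is an implementation constant that no published value
constrains, chosen on synthetic fixtures and exposed in the API.  Third,
the candidate with the brightest *original* intensity wins; ties are broken
by the smallest displacement, then `(row, col)` order.  With no candidates
the marker stays put.  The recorded accuracy of a marker is the Euclidean
distance between its initial and refined positions.  `sigma` defaults to
5 px and is deliberately configurable: it should be of the order of the
operator's placement error.  Seed markers are refined by the same
procedure as tip markers.

# Root tracing

## Polarity

One source text convention says roots have *lower* intensities when costs
are computed, another picks the *brightest* pixel when refining markers.
Both are honoured by fixing a single working raster `R` in which roots are
bright: marker refinement uses `R` directly, and tracing uses the
cost-intensity `I = 255 - R`, in which roots are dark and therefore cheap.

## Cost function

The cost of entering a pixel of cost-intensity `I` is piece-wise linear:

$$E(I) = \begin{cases} aI, & I \le B \\ A(I - B) + aB, & I > B \end{cases}$$

continuous at `B` and strictly increasing.  On-root pixels fall below `B`
and pay the shallow slope `a`; off-root pixels pay the steep slope `A`.
The defaults `a = 1`, `A = 10` are not canonical values — the original
slopes were chosen by eye and never published — and both are exposed.
`B = "auto"` is resolved by a two-stage Otsu threshold of the working
raster (`root_threshold()`): a cropped plate has *three* intensity classes
(black exterior, paper, bright roots), so a single Otsu pass tends to
separate the exterior from everything else; a second pass above the first
threshold separates roots from paper.  The second pass is skipped when the
first already isolates a small bright class.

## Front propagation and backtrace

For each seed, Dijkstra's algorithm propagates a front over the *entire*
raster (8-connected by default; 4-connected available), each step into
pixel `q` costing `E(raster[q])` times the step length (1 axially, the
square root of 2 diagonally).  Exploring the whole image is deliberately
inefficient but cannot miss the global minimum.  A tiny floor
(`min_step_cost = 1e-8`) keeps every step strictly positive: saturated
pixels otherwise have cost exactly 0, producing plateaus on which a
gradient descent could stall.  The floor is many orders of magnitude below
any real intensity cost.

A root path is recovered from a tip by repeatedly stepping to the
strictly-cheapest 8-neighbour until the seed (cost 0) is reached.  On a
valid Dijkstra map every non-seed pixel has a strictly cheaper neighbour,
so the descent terminates; ties (possible on exactly symmetric rasters)
prefer the neighbour nearest the seed, then `(row, col)` order — the
plateau behaviour of the original is unspecified, so these rules are this
package's own convention, chosen to be deterministic.

## Tip–seed association

Every tip is costed against every seed's map and assigned to the seed of
minimal accumulated cost; its path is then backtraced on that seed's map
(backtracing only the winning map gives the identical result to backtracing
all maps and pruning, at a third of the cost).  Cost ties go to the nearest
seed by Euclidean distance, then the lowest seed index.  Any number of
seeds is supported; tips unreachable from every seed are excluded and
reported.

# Traits

Root length is the sum of Euclidean distances between consecutive path
pixels, times the scale.  Angles are measured on straight segments from the
seed, relative to the downward vertical, positive clockwise, in
(-180, 180].  The cereal ("barley") convention reports root count,
individual/total/mean/longest lengths, and two spread angles: *basal*,
the max-minus-min of the per-root angles measured to the point at 10% of
each root's arc length, and *apical*, the same on seed-to-tip segments.
The "10% of the length" is interpreted per root (the phrasing for the
primary-root convention is unambiguous on this point, and the same reading
is applied to both); the fraction is exposed as `angle_fraction`.  The
"solid angle" terminology is retained in the CSV headers for continuity
with the assay literature although the measured spread is planar.  The
oilseed-rape ("brassica") convention reports the primary root — the longest
path — with its length and its angles from the vertical at the seed (10%
point) and at the tip.  A seed is germinated if it has at least one
associated tip; ungerminated seeds carry zero counts and unset lengths and
angles.  Genotype summaries report, per trait, the mean and the standard
error of the mean (sample SD divided by the square root of n) over
germinated seeds, with n reported; a single observation leaves the SE
unset with a warning.

# Quality control

## Error typology

Four error classes are recognised, matching the field's taxonomy of
semi-automatic tracing failures: *shortcut* (the path cuts off-root,
typically across a bend — the characteristic failure of cost-optimal
tracing, which underestimates length), *convergence* (two traces share one
root, typical at crossings), *wrong association* (a tip assigned to the
wrong seed) and *misadjustment* of a tip marker, subdivided into
*misplacement* (on the wrong root), *not on root*, and *not on tip*.  The
original classification was done by human inspection; `classify_errors()`
operationalises it with tolerance-based geometric rules against the
generator's ground truth (defaults: tolerance 3 px, convergence when more
than half of a path's pixels lie within tolerance of another traced path,
shortcut when more than 10% lie farther than tolerance from every true
polyline), applied in a fixed priority order so classes are mutually
exclusive per path.  These thresholds are this package's interpretation
and are config-exposed.

## Outlier flags

`flag_outliers()` screens batches with three histogram-style rules — root
count per seed, total root length, and tortuosity (path length over
seed-to-tip chord; 1 for a straight root, per-seed statistic the maximum
over paths) — flagging values outside median plus or minus `k` MADs
(default `k = 3.5`, the conventional robust cut-off).  The rules mirror
the screening histograms proposed for this assay, which name no statistic;
the MAD rule is this package's choice.  Flags are advisory: extreme true
phenotypes will trip them too.

## Baseline measurement

`baseline_total_length()` implements the fully automatic benchmark: red
channel; median then Gaussian filter of radius 0.16 mm (the Gaussian
"radius" is taken as its sigma in px); background subtraction with a
median filter of 2.6 mm diameter; maximum-entropy (Kapur) threshold;
morphological thinning (Zhang–Suen) to a 1-px skeleton; and total length
as the skeleton's step length (diagonal adjacencies count the square root
of 2, except where an axial pixel already bridges the pair) times the
scale.  Two numerical guards matter on clean synthetic input: residuals
below one 8-bit level are zeroed (filtering leaves FFT-scale residue
everywhere), and the entropy threshold is computed over positive residuals
only, because the background-subtracted image is mostly *exact* zeros — a
histogram shape Kapur's criterion was never meant to see.  A border frame
of the background-filter radius is blanked to remove the paper-rim
subtraction artefact.

# The synthetic generator

`render_plate()` draws a warm dark background, a blue paper square, roots,
a barcode label and additive Gaussian noise.  Roots are quadratic Bezier
chains sampled at ~1 px arc-length steps, rendered as anti-aliased
polylines about 3 px wide and *brighter* than the paper by a configurable
contrast — thin, curvilinear, contrast-limited structures, which is exactly
what the tracing stage assumes.  The generator's defaults are the study
conditions used by the test suite: three seeds, three roots per seed,
curvature 0.15, contrast 0.6, noise SD 0.05 (on a 0–1 intensity scale).

Design choices that matter for verification:

* **Truth on the discrete metric.** Ground-truth polylines are stored as
  8-connected integer pixel chains (axial L-corners collapsed into diagonal
  steps).  Any 8-connected pixel path measures length on the octile metric,
  which exceeds the smooth arc length by up to 8.2% for oblique directions;
  digitising the truth the same way makes "traced length within 2% + 3 px
  of truth" a meaningful contract instead of a metric artefact.
* **No accidental crossings.** Each seed's roots are confined to a lateral
  band halfway to its neighbours, and same-seed roots keep a minimum
  separation (curvature is damped and, as a last resort, a root is
  truncated or dropped).  `crossing_prob` then *causes* crossings
  deliberately: within a seed by swapping the endpoints of an adjacent root
  pair, and between adjacent seeds by swapping the endpoints of their
  facing roots — the latter reproduces the wrong-association phenomenology.
  A consequence is that a seed can carry fewer roots than requested when
  its band is crowded.
* **Hue-stable background.** The background colour is warm and saturated
  enough that additive channel noise cannot flip its hue across the Otsu
  split of the hue histogram (a neutral gray background has undefined hue
  and percolates through the segmentation under noise).

What the generator does **not** emulate: paper texture, condensation and
lid reflections, shadows, lens distortion, root hairs, branching (laterals)
and width variation along the root.  Passing tests therefore demonstrate
the algorithmic contracts — metric correctness of the cost map, associative
pruning, trait geometry, error detection — not robustness to photographic
artefacts of real dishes.

# Test and benchmark sizes

The suite works at desk scale, chosen to keep the default test run within
minutes: frames of 480 x 640 px with a 400-px paper (0.2475 mm/px, about
40% of the physical assay's resolution); 50 noise-free plates for the
length-recovery and association checks plus 25 plates with crossings; 20
plates for the ingestion round trip; 100 random grids up to 15 x 15 for
the Bellman–Ford equivalence; 8 plates per noise level for the
monotone-difficulty trend.  `scripts/acceptance.R` re-runs the same
pipeline on freshly generated suites and writes the measured quantities as
JSON.

# Known limitations

* The tracer requires markers; there is no automatic tip/seed detection.
* Shortcut bias is inherent to cost-optimal tracing: at low contrast a
  tightly curved root is traced short (the package reproduces this
  deliberately, and the error classifier reports it).
* Shared-path costs are not implemented, so crossing roots can converge
  onto one stem (again reported, not corrected).
* The barcode symbology is self-contained: labels printed as genuine QR
  codes require an external decoder upstream.
* Real-image robustness (shadows, reflections, texture) is outside what
  the synthetic suite can certify.
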