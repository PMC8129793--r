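---
title: "Quantifying collective border cell migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective border cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bordercell)
```

## The measurement problem

A migrating border cell cluster is scored along three axes: how far it got
(migration index), how fast and how directed it moves (forward speed,
tumbling index), and how polarized its actin machinery is (front/side/back
protrusion statistics, back/middle/front line-scan fractions). All of these
reduce to operations on binary masks and intensity profiles extracted from
calibrated fluorescence images. This vignette records the model behind each
operation, the tunable parameters, and the design decisions taken where the
underlying experimental practice is manual or unpublished.

Throughout, images are matrices with x rightward and y downward, pixel
centres at half-integer multiples of the pixel size, and all physical
outputs in micrometres and minutes. After orientation the anterior end of
the egg chamber is at the left, so the leading edge of migration points
along +x and angles are measured counterclockwise from it.

## Segmentation model

The cluster is assumed to be the single dominant bright object in a
background-subtracted, maximum-projected frame. `threshold_cluster()`
binarizes with Otsu's criterion on the min–max-normalized image (an
absolute threshold is available as an override) and keeps the largest
connected component. The normalization makes the mask exactly invariant
under multiplicative intensity changes, and replacing interactive manual
thresholding with Otsu trades operator judgement for reproducibility — the
threshold used is recorded on the mask.

`split_body_extensions()` separates body from protrusions by morphological
opening with a disk. The default opening radius is half the equivalent
radius of the full mask (`0.5 * sqrt(area / pi)`), a scale-free choice that
needs no retuning as clusters grow or shrink; it can be fixed in µm
instead. Residual components smaller than `min_extension_area` (default
2 µm², i.e. a few pixels at 0.62 µm/px) are folded back into the body, so

```
area(body) + sum(area(extensions)) == area(full mask)
```

holds exactly — the partition is an invariant, not an approximation.

## Protrusion sectors and motility

Extension angles are measured from the full-cluster centroid to the
extension centroid. The centroid (rather than the protrusion tip) is
deliberately robust to ragged mask boundaries. Sector boundaries are
half-open and left-inclusive — 45° is a side, 135° a back, 315° a front —
so the three sectors tile the circle with widths 90/180/90 and no angle is
double-counted.

Forward speed is the mean of consecutive-frame x increments divided by the
frame interval, which equals net displacement over total time for the same
window; the default window is the whole movie. Sector statistics are pooled
over all frames of a movie by default (a per-frame table is returned, so
per-movie means are one `aggregate()` away).

### Tumbling

"Tumbling" needs two operational definitions the bench protocol leaves
informal:

* **Rounded** — circularity `4 * pi * A / P^2` at or above 0.85
  (configurable). The perimeter comes from the 8-connected boundary chain
  with Kulpa's correction factor `pi * (1 + sqrt(2)) / 8`, which keeps the
  estimate within ~1% of the true perimeter for smooth shapes; a large
  rasterized disk scores ≥ 0.98 and a 10:1 bar ~0.39, so 0.85 cleanly
  separates protrusion-free bodies from protrusive ones.
* **Rearranged** — nuclei are detected as local intensity maxima inside the
  body (Gaussian pre-smoothing at 0.6 µm, minimum separation 2 µm,
  relative threshold 0.3 of the median-to-max body range), identity-matched
  between consecutive frames by greedy closest-pair assignment, and sorted
  by angle around each frame's own centroid. A transition is a
  rearrangement when the cyclic order of identities changes; rigid
  translations of the whole cluster therefore never count. Greedy matching
  is used instead of plain per-point nearest neighbour because it keeps
  identities correct whenever each nucleus moves less than the distance to
  its neighbours' new positions — the regime time-lapse imaging at
  3 min/frame operates in.

A frame is *tumbling* when it is rounded and involved in a rearrangement
with either adjacent frame, and belongs to a run of at least two
consecutive such frames (single-frame blips are ignored). The index is the
percentage of tumbling frames within the first half of migration, defined
by default as the first `ceiling(T/2)` frames of the analyzed movie — the
alternative split at 50% migration index is exposed via the `first_half`
argument. Mapping the per-transition rearrangement calls onto frames via
*either* adjacent transition means a continuous tumbling episode marks
every frame it spans, so a movie whose entire first half tumbles scores
exactly 100%.

## Line-scan polarity

`extract_line_profile()` averages `width` (default 3) parallel bilinear
samples perpendicular to the scan line. Peaks are local maxima with
prominence at least 10% of the profile's dynamic range (default). Each
peak's support runs between its flanking minima, truncated at midpoints
between adjacent apexes so supports never overlap; the area is the
trapezoidal integral above the linear baseline joining the support
endpoints, with negative excursions clamped. Against a single sampled
Gaussian this recovers the closed-form area `A * sigma * sqrt(2 * pi)`
to well under 5% at ≥ 8 samples per sigma. The local linear baseline — as
opposed to a global constant — keeps areas honest on tilted backgrounds,
at the cost of a small tail loss when peaks crowd together (see
limitations).

BMF fractions assign each peak to the back/middle/front by apex position in
the first/second/last third of the user-supplied cluster extent — the
thirds rule is our operational reading of an otherwise unstated
"back/middle/front" assignment — and normalize per cluster by total peak
area. Per-cluster normalization (rather than per-genotype) was chosen
because it makes each cluster's fractions a self-contained observation that
replicate summaries can average.

Mosaic ratios use mean intensity or raw integrated density over
user-supplied sibling-region masks; the fold is reported as control/test
when the test region is dimmer so that reductions read as folds > 1.

## Promoter windows

Promoter windows span −1000..+200 bases around the TSS in 0-based
half-open coordinates (a 1200-base window; the 1-based TSS input is
converted internally). For minus-strand genes the window is mirrored so
−1000 is upstream *in the direction of transcription* — the biologically
standard reading; `strand_aware = FALSE` reproduces the strand-naive
alternative. A peak overlaps a window when they share at least one base on
the same chromosome; touching intervals do not overlap under half-open
arithmetic, a convention the fixture generator exercises explicitly. A
peak hitting several windows counts for every gene. The overlap engine is
IRanges; the test suite checks it against brute-force all-pairs
computation on fixtures up to 10⁴ intervals.

## The synthetic-data generators

The generators exist so that every measurement has a known answer. They
emulate:

* a cluster as a blurred disk (default radius 9 µm at 0.62 µm/px — a
  conventional 20x-objective calibration, configurable) with protrusion
  lobes, nuclear spots, and additive Gaussian noise;
* motion at a configurable forward speed with 3 min frame intervals, the
  standard culture-imaging cadence; default speeds of 0.45 and
  0.09 µm/min correspond to healthy and strongly impaired migration;
* protrusion sectors drawn from front/side/back weights (default
  0.54/0.30/0.16, a healthy front bias), with angles uniform within the
  sector and a 25° minimum separation so rendered lobes stay disjoint;
* tumbling episodes: protrusions suppressed (the body renders rounded) and
  one nucleus relocated to a vacant angular slot per transition, redrawn
  until the cyclic order provably changes. Relocation-to-a-vacant-slot was
  chosen over a literal position-exchange between two nuclei because an
  exact exchange is invisible to *any* proximity-based identity matching —
  the matcher reassigns identities rather than observing the crossing —
  whereas a single relocation among otherwise near-static nuclei is
  detected reliably;
* tri-Gaussian line profiles whose analytic areas are in the requested
  BMF ratios; mosaic half-disk pairs at an exact intensity fold; and
  BED/gene fixtures whose overlap truth is computed by brute force at
  generation time.

Ground truth (masks, angles, areas, tracks, flags) is recorded *before*
blur and noise. All randomness flows through one seed per generator call,
and the caller's RNG state is restored afterwards; identical seeds give
bit-identical outputs.

What the generators do **not** emulate: realistic 3-D optics (the PSF is a
single 2-D Gaussian, default 0.8 µm), photobleaching, z-drift,
multi-channel crosstalk, nurse-cell background texture, or
partially-detached cluster geometries. Passing the recovery suites
therefore demonstrates that the *measurement* chain is correct and
well-calibrated on images whose difficulty (SNR 10–30, subpixel motion,
crowded nuclei) is in the realistic range — not that segmentation would be
unattended-reliable on every real acquisition.

## Numerical choices and degenerate inputs

* Otsu on a constant image, an empty foreground, an opening that erases
  the whole mask, a track that exits the frame, or a protrusion longer
  than the image all fail fast with specific errors (the offending frame
  or a remediation hint named).
* Empty extension lists yield `NA` sector percentages — missing, not 0.
* Zero total peak area yields `NA` BMF fractions.
* `migration_index()` clamps to [0, 100]: positions beyond the boundary
  are complete migration.
* Circularity is clamped at 1 to absorb residual discretization error.
* Unequal nucleus counts between frames are compared on the greedy-matched
  common subset, with a message.

## Problem sizes

The shipped tests and the acceptance script run on 120–160 px square
frames, 12–20 frame movies, 240-point profiles, and fixtures of up to 200
genes x 5000 peaks per replicate — sizes at which the full suite completes
in well under a minute while exercising subpixel motion, blur, noise and
crowding. All generators scale to larger canvases by changing the specs.

## Known limitations

* The body/extension split inherits the opening radius: protrusions wider
  than twice the radius are absorbed into the body. The scale-free default
  handles typical lobe geometries; unusually broad lamellipodia need a
  larger explicit radius.
* Peak areas lose a few percent of tail area to the local baseline when
  peaks are separated by less than ~5 sigma; noise-free BMF recovery is
  within 2 percentage points under the default geometry, and the
  generator records a warning flag when peaks overlap materially.
* Rearrangement detection assumes nuclei are individually resolvable
  (≥ ~2 µm apart) and that per-frame motion is small relative to
  inter-nucleus spacing; it reports order changes, not which cells moved.
* Scan lines, mosaic region masks and junction masks are inputs, as they
  are drawn manually at the bench; the package does not auto-place them.
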