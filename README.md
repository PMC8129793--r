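# bordercell

Quantification of collective border cell migration from fluorescence
microscopy.

During *Drosophila* oogenesis a small cluster of border cells detaches from
the follicular epithelium and migrates between the nurse cells to the
oocyte. How far, how fast and how *directed* that migration is — and how
polarized the cluster's actin protrusions are — is the standard phenotypic
readout for genes controlling collective cell migration. `bordercell`
implements the image-quantification side of that assay as a reusable,
tested R package, for researchers who would otherwise rely on one-off
ImageJ macros:

* **Segmentation** — maximum z-projection, anterior-left orientation,
  background subtraction, cluster thresholding (Otsu or absolute), and
  morphological splitting of the cluster mask into cell **body** and
  **cellular extensions** (protrusions).
* **Protrusion polarity** — each extension gets a centroid angle relative
  to the cluster centre (0° = leading edge, counterclockwise) and a sector
  label: front (315–45°), side (45–135° or 225–315°), back (135–225°),
  with half-open, left-inclusive boundaries.
* **Motility metrics** —
  * forward-directed speed: mean over consecutive frames of
    Δx / Δt (µm/min, positive toward the posterior);
  * migration index: 100 · (x − x₀) / (x_boundary − x₀), clamped to
    [0, 100];
  * roundness: circularity 4πA/P² of the cluster mask (Kulpa-corrected
    chain-code perimeter);
  * tumbling index: the percentage of first-half frames in which the
    cluster is rounded (circularity ≥ 0.85) *and* its nuclei have changed
    circular order, in runs of at least two consecutive frames.
* **Line-scan polarity** — thick-line intensity profiles, prominence-based
  peak detection, trapezoidal area-under-peak above a local baseline, and
  back/middle/front (BMF) percentages of peak area by thirds of the
  cluster extent; mosaic-clone intensity ratios (mean or raw integrated
  density) and inner/outer junction ratios.
* **ChIP promoter annotation** — strand-aware promoter windows spanning
  −1000..+200 bases around each TSS (0-based half-open arithmetic),
  peak-to-gene assignment per replicate, and per-gene replicate binding
  counts.
* **Synthetic ground truth** — generators for calibrated cluster images,
  time-lapse stacks (including tumbling episodes with nucleus
  rearrangement), tri-peak line profiles, mosaic images and BED/gene
  fixtures, each returning machine-readable truth so every stage is
  testable without microscope data.

## Worked example

Simulate a healthy control movie and a tumbling mutant-like movie, and run
the full analysis on each:

```r
library(bordercell)

ctl <- make_timelapse(cluster_spec(), protrusion_spec(),
                      motion_spec(forward_speed = 0.45, n_frames = 20),
                      seed = 1)
analyze_movie(ctl$stack)
#> <bc_movie_analysis>
#>   frames: 20, extensions: 32
#>   forward speed: 0.433 um/min
#>   tumbling index: 0.0%
#>   sector %: front 46.9 / side 40.6 / back 12.5

mut <- make_timelapse(cluster_spec(), protrusion_spec(),
                      motion_spec_max_tumbling(20), seed = 1)
analyze_movie(mut$stack)
#> <bc_movie_analysis>
#>   frames: 20, extensions: 25
#>   forward speed: 0.109 um/min
#>   tumbling index: 100.0%
#>   sector %: front 40.0 / side 36.0 / back 24.0
```

The control cluster, simulated at a true forward speed of 0.45 µm/min with
front-biased protrusions, is recovered at 0.433 µm/min with no tumbling;
the maximal-tumbling movie (true speed 0.09 µm/min, every first-half frame
rounded with nuclei rearranged) is measured at 0.109 µm/min with a
tumbling index of 100% — the full segmentation, nucleus-tracking and
run-length machinery recovering exactly what was simulated. A speed drop
from 0.45 to 0.09 µm/min is an 80% reduction
(`percent_reduction(0.45, 0.09)`).

A YAML-configurable end-to-end run (`run_pipeline()`) and a thin CLI
(`inst/cli/bordercell.R`, subcommands `run` and `chip`) write the
extensions table, track table, summary JSON and a provenance log.

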