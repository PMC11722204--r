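---
title: "Methods: consensus refinement, blob editing, and trabeculation quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus refinement, blob editing, and trabeculation quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrefine)
```

## The problem

Left ventricular non-compaction (LVNC) is screened by quantifying how much
of the myocardium is trabeculated. Short-axis cine MRI slices are segmented
into four classes — background (BG = 0), compacted external layer (EL = 1),
internal cavity (IC = 2), and trabecular zone (TZ = 3) — and the screening
statistic is the trabeculated volume percentage

$$VT\% = \frac{TZ}{TZ + EL} \times 100,$$

where $TZ$ and $EL$ are class volumes; values strictly above 27.4% are
conventionally taken as hypertrabeculation. The trabecular zone is a
filigree of thin structures, so automatic segmentations of it carry
characteristic errors — misplaced class borders, dropped trabeculae,
hallucinated trabeculae in empty regions — that bias $VT\%$ and corrupt any
training set built from the labels. This package implements the two
refinement mechanisms used to clean such label maps (ensemble consensus
voting and blob-based difference editing), the Dice evaluation used to
monitor them, the $VT\%$ quantification itself, and a synthetic phantom
model that makes every stage testable without restricted clinical data.

## Consensus refinement

In a patient-grouped $k$-fold cross-validation, each training image is seen
by $k-1$ trained models (four, with the default five folds). The consensus
rule operates per pixel, on hard labels: if at least $m$ of the $n$
available predictions assign the same class, that class becomes the new
label; otherwise the original label is kept. `ensemble_set()` enforces
$m > n/2$, which guarantees at most one class can reach the threshold, so
the rule needs no tie-break; the default is the 3-of-4 setting. The rule is
a pure function (`consensus_refine()`), and `refinement_report()` tabulates
the induced label transitions.

Two design points were genuinely open:

- **Hard labels vs class probabilities.** Model ensembles could vote with
  their per-class probability maps. The rule here consumes hard output
  classes, because that is how the correction is defined operationally
  (predictions arrive as label images from arbitrary sources, including the
  phantom simulator) and it keeps the rule independent of any particular
  model's calibration.
- **Generalizing 3-of-4 to $m$-of-$n$.** Fixing $n = 4$ would tie the
  operation to one fold count. The implementation accepts any $n \ge 1$
  with $n/2 < m \le n$; the uniqueness argument above is what makes the
  generalization sound.

`split_folds()` deals shuffled patient identifiers round-robin into folds,
so folds partition patients with sizes differing by at most one and no
patient contributes images to two folds. The shuffle is seeded; the same
seed always reproduces the same assignment.

## Blob-based difference editing

`compute_diff()` marks every pixel where a reference mask and an output
mask disagree with the *reference* class (the class that correcting the
pixel would restore); agreeing pixels carry the sentinel `NA`.
`extract_blobs()` decomposes the difference set into connected components
*per reference class*: two adjacent difference pixels with different
reference classes belong to different blobs, mirroring how differences are
rendered in one color per class. Blobs therefore partition the difference
set exactly, and applying every blob reconciles the output with the
reference bit-exactly; each single application reduces the Hamming distance
by exactly the blob's size. Both properties are asserted in the test suite
against an independent flood-fill oracle.

Numerical and interface choices:

- **Connectivity defaults to 4-connected** (configurable to 8). Diagonal
  contact then separates blobs, yielding more, smaller, more precisely
  selectable regions — the behavior wanted when fixing thin trabeculae by
  clicking. The convention is pinned because component structure depends on
  it.
- **Blob ids are scan-order deterministic** (ordered by each blob's first
  pixel in column-major order), so sessions are replayable and saved
  selections stay valid.
- **Blobs are frozen when a session opens.** Manual painting does not
  trigger re-extraction; applied blobs are tombstoned rather than
  recomputed, keeping ids stable for the lifetime of the session. A session
  records applied ids and paint strokes, and `replay_session()` reproduces
  the current output from that log — `refresh_session()` is therefore a
  true reset.
- **Paint strokes are pixel sets.** Brush shape and rasterization belong to
  a front end; the engine stays headless and exactly testable.
- Internally, components are computed by building the pixel-adjacency graph
  vectorized and labeling its connected components with `igraph`; the test
  oracle is an explicit scan-order flood fill, so the two routes are
  algorithmically independent.

## Dice evaluation

`dice()` computes $2|A \cap B| / (|A| + |B|)$ exactly from pixel counts.
Reports score the three tissue classes EL, IC, TZ — background is excluded,
as is standard for this evaluation — and average the *defined* per-class
values. When a class is absent from both masks the default policy is to
*exclude* that value (`NA`) rather than credit 1.0: apical and basal slices
often contain no trabeculae, and crediting perfect agreement there inflates
averages. The alternative policy (`"one"`) is available because either
convention appears in practice. Aggregation (`aggregate_dice()`) reports
per-group mean and standard deviation per column; the population form
(divide by $n$) is the default and the sample form is a flag, since
published tables rarely state their convention. Averages are computed per
image and then aggregated (rather than averaging per-class means), with the
per-class columns reported alongside so either reading is available.

## Trabeculation quantification

`class_volumes()` integrates per-class pixel counts over a slice stack with
voxel volume `pixel_spacing_row × pixel_spacing_col × (slice_thickness +
slice_gap)`. Using the slice *pitch* (default 8 mm + 2 mm = 10 mm)
attributes the tissue in the inter-slice gap to the adjacent slice — the
standard choice when gapped acquisitions are integrated; the alternative
(thickness only) would systematically under-measure every class by the same
factor and leave $VT\%$ unchanged, which is why the convention matters only
for absolute volumes. Without geometry, volumes fall back to pixel counts;
$VT\%$ is scale-invariant, so both unit systems give the same percentage.

Per-patient $VT\%$ pools TZ and EL volumes across all provided slices
before dividing (a ratio of sums). A mean of per-slice ratios would weight
sparse apical slices equally with dense mid-ventricular ones; a volume
percentage implies pooling. The threshold comparison in `classify_lvnc()`
is strict (`>` 27.4), following the convention that values *above* the
threshold indicate hypertrabeculation; the threshold is a parameter. The
degenerate case $TZ + EL = 0$ yields an explicit `NA`, not an error, so
batch pipelines can flag rather than crash.

## Geometric preprocessing

Workflows that train on these masks upscale them to 800 × 800 and crop
384 × 384 around the left ventricle. `upscale_nearest()` uses
nearest-neighbor sampling with the pixel-center convention — the only
admissible scheme for label maps, since interpolation would manufacture
fractional labels — and, because the target is never smaller than the
source, every source pixel is sampled at least once and the class set is
exactly preserved. `crop_centered()` centers the window on the centroid of
non-background pixels (no extra annotation needed, deterministic), clamps
it to the image bounds, and falls back to the image center with a warning
when there is no foreground; how the crop window was originally positioned
is not specified anywhere, so the centroid policy is this package's
documented choice. The returned offset makes the crop invertible via
`paste_back()`. All coordinates in the package are 1-based row/col with
inclusive windows, matching R's matrix indexing; offsets are defined so the
crop/paste round trip is exact, which the tests assert.

## The phantom model

`generate_phantom()` builds a short-axis slice as concentric structures
around a center: an internal-cavity disk of radius `r_cavity`, a
trabeculated band `(r_cavity, r_band]`, a compacted external-layer annulus
`(r_band, r_outer]`, and background outside. Band pixels not occupied by
trabeculae are labeled internal cavity, as the intertrabecular recesses are
blood-filled. Trabeculae are random disks with radii in
`speck_radius_range` (default 2–6 px), accepted while the trabecular pixel
count is below `round(trab_fill × band_area)`; the final overshooting disk
is trimmed pixel-wise under the same seeded stream, so the achieved count
equals the target exactly and the returned truth counts always match the
mask. The speck-size distribution of real trabeculae is unknown, so the
range is a user parameter rather than a fitted quantity.

`perturb()` models the three error kinds refinement targets, applied in a
fixed, documented order (the steps do not commute) from one seeded stream:

1. **Boundary jitter** — a smooth random warp: offsets drawn on a coarse
   control grid (16 px spacing) in `[-j, j]`, bilinearly interpolated to
   full resolution, then used to resample labels nearest-neighbor. Class
   boundaries move by at most `j` pixels; class labels stay valid by
   construction.
2. **Dropout** — each trabecular connected component is erased with the
   given probability and filled with the majority non-trabecular label of
   its 8-neighborhood (background if none), emulating missed trabeculae.
3. **Hallucination** — a Poisson-distributed number of disks are placed
   only in background regions and labeled trabecular zone, emulating
   hallucinated trabeculae in empty areas.

`simulate_ensemble()` derives $n$ independent members by scaling all
perturbation rates by `1 − agreement` and offsetting the seed per member:
at `agreement = 1` members equal the input exactly, and member similarity
increases monotonically with agreement (tested). This stands in for the
outputs of independently trained networks.

**What the phantoms do and do not show.** They reproduce the *topology* and
label statistics of short-axis LV masks (radial class ordering, tunable
trabeculation fraction, realistic error modes), which is what the
consensus, blob, Dice and VT operations consume — so passing tests validate
those operations exactly. They do not emulate grayscale MRI appearance,
cardiac phases, through-plane anatomy changes, papillary muscles, or the
spatial correlation of real model errors; test results on phantoms
therefore say nothing about the accuracy of any particular segmentation
model on clinical data, only about the correctness of the refinement and
measurement machinery applied to its outputs.

## I/O conventions

Masks are written as 8-bit RGB PNGs using exact palette colors (muted,
colorblind-friendly: EL olive `#808000`, IC cyan `#00B7C7`, TZ rose
`#E6A3B3`; difference rendering green/blue/wine/purple by reference class
with a neutral gray for agreement). Reading inverts the palette exactly and
refuses any off-palette pixel by color and position, so resampled or edited
images cannot be silently misread; round trips are lossless and tested
bit-exact. Slice stacks use NIfTI with 32-bit integer labels; the header's
third pixel dimension carries the slice pitch (thickness + gap), which is
what volume integration needs — the thickness/gap split itself is not
representable in the header and can be restored via a geometry override.
Blind-comparison bookkeeping (`blind_shuffle()`, `selector_record()`,
`record_selection()`) keeps the unblinding key out of the presented
payload, constrains quality scores to the nine half-step values 1.0–5.0,
and appends records to JSONL stores so concurrent raters never corrupt a
shared file and stores merge by concatenation.

## Problem sizes and tolerances in the test suite

The suite validates the consensus rule against an independent per-pixel
vote counter on 200 random 32 × 32 instances and exhaustively over all
$4^5$ single-pixel label combinations; blob partition/convergence on 100
random mask pairs against a flood-fill oracle; Dice on 200 random pairs
against set arithmetic; $VT\%$ recovery on 256 × 256 phantoms at band fills
of 0.1/0.3/0.5 (ten seeds each, recovery is exact by construction and
additionally bounded at ±5 percentage points); and end-to-end refinement
recovery on 20 corrupted phantoms (boundary jitter 2 px, two expected
hallucinations, four-member ensembles at agreement 0.9). These sizes were
chosen as the smallest at which the properties are non-trivial while the
whole suite stays fast on a laptop.

## Known limitations

- 2D slices only; no 3D connectivity across slices (blobs and components
  are per-slice, matching the editing workflow).
- Hard-label voting; probability-map fusion is out of scope.
- The phantom's trabeculae are disks, not branching structures; adequate
  for count/fraction recovery, not for shape statistics.
- No DICOM reading and no grayscale-image processing; the package handles
  label maps only.
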