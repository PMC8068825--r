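---
title: "Counting trapped insects by tiled detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting trapped insects by tiled detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapcount)
```

## The problem

A pheromone trap for the black pine bast scale accumulates hundreds of
~2 mm insects between inspections. Photographed at 6000 × 4000 px, each
insect spans roughly 60 × 60 px — about 0.006 % of the frame. Object
detectors degrade sharply at that relative size, and any detector that is
run on tiles instead produces a new problem: the same insect is seen in
several tiles, and insects cut by tile borders are seen only partially.
`trapcount` implements the counting pipeline around the detector: tiling,
duplicate elimination, counting, and evaluation. The detector itself is an
interface; the trained CNNs used operationally and the two weight-free
detectors shipped here are interchangeable behind it.

## The pipeline

### Scanning grid

Windows of side $w$ are placed every $s = w - v$ pixels, where $v$ is the
overlap (default 100 px). Along an axis of length $L$ there are
$n = \lceil (L - w)/s \rceil + 1$ windows; all offsets are $i\,s$ except
the last, which is clamped to $L - w$ so that every window has full size
and no padding is needed. With $L = 6000, 4000$ this yields 15 × 10 = 150
windows at $w = 500$ and 7 × 5 = 35 at $w = 1000$.

The clamped-grid construction gives a containment guarantee: any object
with both sides at most $v$, anywhere in the image, lies wholly inside at
least one window. Proof sketch: take the right-most window offset
$o \le x_{\min}$; then $x_{\min} < o + s$, hence
$x_{\max} \le x_{\min} + v < o + s + v = o + w$. The overlap was chosen
larger than the insect precisely so this holds, and the property test in
the suite exercises it with 10,000 random boxes.

### Duplicate elimination

Two distinct mechanisms produce duplicates, and each needs its own remedy:

* An insect wholly inside the overlap region of two windows is detected
  twice at (nearly) the same place. Global greedy NMS removes such
  duplicates: detections are visited by descending score and any remaining
  detection with IoU strictly above the NMS threshold (default 0.5) with a
  kept one is discarded.
* An insect **cut** by a window border yields a partial box whose IoU with
  the full box from the neighbouring window is low — typically below any
  sensible NMS threshold — so NMS cannot remove it. Instead, any box whose
  coordinate lies within a tolerance (default 1 px) of a window border is
  dropped before pooling. Borders that coincide with the image boundary
  are exempt: an insect at the trap's perimeter is cut in *every* window
  that sees it, and the literal rule would make it uncountable. The
  exemption is the minimal reading that preserves the rule's purpose; it
  is exposed as a switch (`filter_edges`) so the literal behaviour can be
  reproduced.

The containment guarantee makes the edge filter safe: a box discarded at
an interior border is always intact in an adjacent window (provided its
sides are at most `overlap - tolerance`).

### Counting and threshold calibration

Detections surviving stitching are counted if their score reaches the
score threshold. The threshold acts downstream of a fixed detection stage,
so a trap is stitched once and re-counted at any threshold for free; the
calibration routine exploits this to sweep a 0.05-spaced grid
(0.05–0.95 by default) over a calibration subset of traps — the original
design reserves 10 of 30 traps for this — and returns the threshold with
the smallest counting error, ties resolved toward the higher (more
conservative) threshold.

## Evaluation metrics

Matching is greedy in score order: each detection takes the unmatched
ground-truth box of highest IoU if that IoU reaches the matching threshold
(0.5 and 0.3 are both reported; localization accuracy matters less for
counting than for general detection). Ties on IoU go to the lower truth
index, score ties to input order — both fixed for determinism. The
identities $TP + FN = \#\text{truth}$ and $TP + FP = \#\text{detections}$
hold for every input and are property-tested.

AP is the exact area under the monotone (right-to-left running maximum)
precision envelope of the all-point PR curve, with operating points at
the distinct detection scores (a threshold placed at a tied score retains
all of its ties). Greedy score-order matching is prefix-consistent, so
the curve from one full match's cumulative TP counts equals re-matching
each thresholded subset from scratch; the test suite checks this
equivalence against a brute-force sweep on 200 random instances.

The counting error is implemented as the mean absolute per-trap relative
deviation
$\frac{1}{N}\sum_i |C_i - \hat C_i| / C_i \times 100$.
A signed variant (no absolute value, so over- and under-counts cancel) is
available behind `signed = TRUE`, but the absolute form is the default:
a signed mean would report near-zero error for a detector that badly
over-counts sparse traps and under-counts dense ones. Traps with
$C_i = 0$ are rejected rather than silently skipped.

## The reference detectors

**Blob detector.** Grayscale conversion (luminance weights), intensity
threshold (fixed 0.5 by default, per-tile Otsu available), connected
components, area filter. The score is the component's mean contrast
against the median tile background, clipped to $[0,1]$ — any monotone
confidence suffices for threshold calibration. Insects that touch merge
into one component, so the detector estimates each component's
multiplicity as $k = \mathrm{round}(A / A_1)$, where $A_1$ is the
single-insect unit area, and splits the component's box into $k$ equal
boxes along its longer side. The unit area is taken per tile as the
median area of components clear of the tile border (cut components have
truncated areas and are excluded; they are removed by the edge filter
anyway), or — more robustly, since sparse tiles give noisy medians —
measured once on a calibration trap with `calibrate_unit_area()`.
Insect-to-insect area variation stays well below the ×1.5 splitting
boundary, so isolated insects are not split; deeply overlapped pairs
whose union area falls below 1.5 units remain undercounted, which is the
detector's residual error mode on clustered scenes.

**Noisy oracle.** Sees the ground truth clipped per window (so cut
insects produce exactly the partial boxes the edge filter exists for),
drops each visible box with probability `miss_rate`, jitters coordinates,
scores true and spurious boxes from separate uniform laws, and adds
Poisson-distributed false positives per tile. Each window's random stream
is derived from the detector seed and the window's grid indices, making
results independent of processing order. With all rates zero it is the
perfect oracle: the pipeline must then return the exact ground-truth
count, and does, on every tested scene whose insects are smaller than the
overlap and clear of the image boundary.

## The synthetic scene generator

The generator emulates the statistical structure of real trap
photographs: a bright yellow background with Gaussian pixel noise
(sd 0.02); insects as dark rotated ellipses whose bounding boxes average
60 px (sd 4 px) on a side, with aspect ratios 0.65–0.95; per-trap
densities stratified below 300 / 300–500 / above 500; a configurable
fraction of insects placed within one insect-diameter of a mate, forming
the overlapped clusters responsible for most counting errors in practice;
and bright elongated wing-like distractors that are rendered but never
annotated, emulating the dominant false-positive source. Ellipse
semi-axes are scaled so each insect's rotated bounding box has the drawn
size exactly, keeping the annotation statistics calibrated. Insects
outside clusters are placed with disjoint boxes (2 px gap), so
`cluster_fraction = 0` produces scenes the blob detector counts exactly —
the generator's own census (its truth list is exact by construction)
anchors every end-to-end test.

What the generator does **not** model: perspective and lens distortion,
lighting gradients from the photographic rig, debris and non-target
insects with insect-like darkness, and photorealistic insect texture.
Passing tests therefore demonstrate the correctness of the pipeline's
geometry, bookkeeping and metrics, and the achievable accuracy under
controlled degradation — not field performance of any particular
detector.

## Problem sizes and numerical choices

* Scenes in tests and the acceptance script are rendered at 1/4 scale
  (1500 × 1000 px, 15 px insects, 125/25 px windows) or 1/10 scale
  (600 × 400 px, 6 px insects, 50/10 px windows), preserving the
  insect:window ratio of the full-scale design; full 6000 × 4000 rendering
  is available via `scale = 1`. The stratified benchmark uses 3 traps per
  density band with 10 % clustering and 20 distractors per trap — a
  moderate degradation level: clusters drive most real errors but affect
  a minority of insects.
* Coordinates are 0-based, half-open, real-valued; widths are
  $x_{\max} - x_{\min}$ with no "+1". Pascal-VOC XML is written and read
  in its conventional 1-based inclusive dialect and converted at the
  boundary; COCO JSON uses `[x, y, w, h]` directly.
* NMS suppression uses strict ">" (a pair exactly at the threshold
  survives); the NMS threshold itself defaults to 0.5 and is deliberately
  configuration, not a constant of the method.
* Degenerate (zero-area) boxes are rejected at construction; empty
  denominators in precision/recall return `NA`, never a silent 0; AP
  without ground truth is an error, while AP of an empty detection set is
  0.
* All generators and the noisy oracle are seeded; identical configuration
  and seed give bit-identical images, annotations and CSV outputs.

## Known limitations

The edge filter assumes detector boxes land within `tolerance` (1 px) of
the border when an object is cut; a detector that hallucinates the hidden
part of a cut object past the border would evade it. Area-based
multiplicity splitting positions the $k$ split boxes geometrically, not
by appearance, so split-box localization is approximate (it suffices for
counting and for AP at IoU 0.3). Counting error is undefined for traps
with zero manual count. Multi-class counting and rotated boxes are out of
scope.
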