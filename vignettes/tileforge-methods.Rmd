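---
title: "Scoring and extracting whole-slide-image tiles with IoT and BoT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and extracting whole-slide-image tiles with IoT and BoT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tileforge)
```

## The problem

Deep-learning pipelines for digital pathology rarely see a whole slide at
once: a gigapixel scan (up to ~100,000 × 100,000 px at 40x) is partitioned
into small square tiles — here 512 × 512 px — and models train on tiles.
When a pathologist has outlined regions of interest (say, tumor), the naive
question "is this tile inside the annotation?" has no good binary answer:
tumor outlines are irregular and frequently concave, so tiles straddling the
boundary are partly positive tissue, and heuristics that probe a handful of
points (the tile's four corners and four edge midpoints) can declare a tile
"fully inside" a concave region that in fact excludes part of it.
Separately, even deep inside an annotation, many tiles are mostly blank
glass or fat and are noise for training.

`tileforge` scores every grid tile with two fractions and gates extraction
on both:

* **IoT (intersection over tile)** — `area(A ∩ T) / area(T)`, the fraction
  of the tile box `T` covered by the annotated-region union `A`. It is 1
  exactly when the tile is contained in the region (touching the boundary
  from inside included), 0 exactly when tile and region are disjoint or
  touch only from outside, and strictly between otherwise. Unlike the
  symmetric IoU, it is normalized by the tile's own area, so it is invariant
  to joint rescaling of the coordinates.
* **BoT (background over tile)** — the fraction of the tile's pixels
  classified as blank background by a fixed image pipeline (below). Its
  complement `ToT = 1 − BoT` is the tissue fraction the gate actually
  compares.

A tile is extracted iff `IoT ≥ iot_thresh` and then `1 − BoT ≥ tot_thresh`,
both comparisons inclusive, in that order: BoT costs a pixel read and a
segmentation, so it is only computed for tiles that already pass the purely
geometric IoT gate. Holistic (annotation-free) extraction applies the BoT
gate alone.

## Exact IoT geometry

Annotations arrive as polygons (ASAP XML, GeoJSON, or a plain-JSON
interchange), possibly with holes, in level-0 pixel coordinates.  After
validation — self-intersecting rings are decomposed into their covered
lobes under the nonzero fill rule rather than rejected, since hand-drawn
outlines commonly self-touch — all regions matching the requested labels
are merged into one polygonal union. Scoring against the union, not
per-region, means overlapping annotations of the same class can never push
IoT above 1.

`compute_iot()` clips each ring of the union against the axis-aligned tile
box with Sutherland–Hodgman half-plane clipping in double precision and
sums the signed clipped areas (holes carry negative orientation and
subtract automatically). Two numerical choices matter:

* **No coordinate quantization on the scoring path.** General
  polygon-boolean engines snap coordinates to an integer grid scaled from
  the data range; that snap moves with the data range, which would make IoT
  drift at the ~1e-6 level under coordinate rescaling. Half-plane clipping
  uses only interpolation in doubles, so IoT is invariant under joint
  scaling and translation of tile and region to better than 1e-9, and the
  clipping engine is reserved for operations where general booleans are
  unavoidable (overlapping-region unions, ring repair). When selected
  regions have pairwise disjoint bounding boxes their rings are
  concatenated verbatim, keeping the common case bit-exact.
* **Limit snapping.** Round-off within 1e-9 of 0 or 1 is snapped to the
  limit, then the value is clamped to [0, 1]; at pixel scale this makes the
  containment and disjointness limit values exact without hiding genuine
  partial overlaps. Tiles are half-open boxes `[x, x+w) × [y, y+h)`, so
  grid tiles partition the plane and a region touching a tile's edge from
  outside contributes zero area, scoring exactly 0.

The exact path is cross-checked by an independent brute-force oracle,
`rasterized_iot_oracle()`: the fraction of a `g × g` grid of pixel-center
sample points inside the union under the even-odd rule (evaluated by
analytic scanline crossings, which counts the identical set of sample
points without per-point loops). Its discretization error is bounded by
about `2/g` for tile-scale shapes; the test suite holds exact-vs-oracle
agreement to `2/2048 + 1e-6` over 200 randomized polygon/tile pairs
including concave crescents.

## The background pipeline

`compute_bot()` runs a fixed sequence per tile: Gaussian blur (5 × 5
kernel; sigma derived from the kernel size as `0.3·((k−1)/2 − 1) + 0.8`, so
results are reproducible across backends) → RGB→HSV → background predicate
→ binary mask → one 3 × 3 box dilation to patch minor mask defects → area
measurement. Tunable parameters, all in `background_params()`:

| parameter | default | meaning |
|---|---|---|
| `blur_kernel` | 5 px | Gaussian pre-smoothing; suppresses single-pixel noise |
| `sat_max` | 20 (of 255) | background candidates must be near-grey: saturation ≤ `sat_max` |
| `val_min` | 235 (of 255) | …and bright: value ≥ `val_min` |
| `dilate_kernel`, `dilate_iters` | 3 px, 1 | minimal morphology to close pinholes |
| `area_mode` | `contour_fill` | how the mask becomes an area (below) |

The thresholds target the white glass of an H&E slide: blank background is
bright and unsaturated, while hematoxylin/eosin-stained tissue is strongly
colored and fails the predicate by a wide margin. They are defaults, not
constants — scanners differ, and both are exposed in the config. The two
area modes agree exactly on hole-free masks; `contour_fill` fills the
external contours of background blobs so that enclosed specks inside a
blank area still count as background, while `pixel_count` is the plain
count and is the more predictable choice for tests.

BoT is 1 exactly on an all-background tile and 0 exactly on an all-tissue
tile. On mixed tiles the blur and dilation perturb only a band of a few
pixels around color boundaries, so block-colored tiles score their ideal
area fraction within ~0.01–0.03 depending on boundary length; this is why
the extraction gate's behavior is only guaranteed for tiles whose tissue
fraction is not within that band of the threshold (see fixtures below).

## The extraction loop

`partition_grid()` tiles the slide from the top-left corner in non-
overlapping steps of the tile size; partial tiles at the right/bottom edges
are dropped so every tile has the full fixed dimensions (fixed input shape
is what downstream training needs). `extract_annotated()` then walks the
grid in deterministic row-major order: IoT gate, pixel read, BoT gate.
Every grid location gets exactly one manifest record carrying the scores
that were actually computed — `bot` stays `NA` for geometry-rejected tiles
(the loop never reads their pixels, which the test suite asserts via the
slide handle's read counter), and in holistic mode `iot` is `NA`, not 0,
to distinguish "not computed" from "computed zero".

Random subsampling (`sample_fraction`, e.g. a 10% draw from negative
slides) keeps `round(n · fraction)` tiles, at least one, reproducibly for a
fixed seed. By default it is applied after the BoT gate, so the sampled
tiles are guaranteed non-blank; `sample_stage = "before_bot"` instead
samples the geometry-passing locations before any pixels are read, which is
cheaper when most of a slide would pass. Both orders are exposed because
either is defensible; "after" is the default since a blank tile that
survives sampling is pure noise.

`extraction_presets()` packages the standard threshold ladder — eight
training configurations A(0.1, 0.0), B(0.2, 0.0), C(0.2, 0.2), D(0.2, 0.5),
E(0.5, 0.2), F(0.5, 0.5), G(1.0, 0.2), H(1.0, 0.5) as (IoT, 1−BoT) pairs,
plus a (0.3, 0.3) testing preset. Because both gates are inclusive and
monotone in their thresholds, the extracted set under any
threshold-nondecreasing pair of presets is a subset of the laxer one's; the
suite asserts this subset relation across the whole ladder.

## What the synthetic fixtures do and do not show

`generate_fixture()` builds deterministic pyramidal slides (8-bit RGB
multi-page TIFF, uncompressed, levels 2× mean-pooled) with rectangle,
ellipse, or crescent "tissue" blobs on a near-white canvas, a matching
annotation file, and a per-tile ground-truth table: exact IoT (closed form
for axis-aligned rectangle annotations, the rasterized oracle at g = 4096
otherwise), the exact painted tissue fraction, and the expected decision
under every preset. Builtin cases: `basic` (grid-aligned square: IoT ∈
{0, 1}), `offset_grid` (square offset by half a tile: IoT ∈
{0.25, 0.5, 1} over a 3 × 3 block, giving the 9/9/5/1 count ladder at IoT
thresholds 0.1/0.2/0.5/1.0), `checkerboard` (decisions driven purely by the
background gate), and `concave` (below).

Two deliberate margin rules keep ground truth honest rather than tuned:
blob colors must sit firmly on one side of the HSV predicate (≥ 30 units on
the channel that rejects them; the background side must satisfy the
predicate outright — with `sat_max` = 20 a 30-unit saturation margin is
arithmetically impossible for any background color, so the wide margin is a
tissue-side requirement), and a preset decision is recorded as `NA`
("undecidable") when a tile's ideal tissue fraction lies within 0.03 of
that preset's threshold without being exactly 0 or 1 — e.g. the offset
square's half-covered tiles against the 0.5 presets, where the measured BoT
sits inside the blur boundary band and an "expected" decision would be a
coin flip dressed up as ground truth. End-to-end tests assert every
decidable tile, 504 of 512 tile-decisions across the four cases.

The fixtures emulate geometry and color classes only: uniform blobs, hard
edges, no stain texture, no scanner noise, no pen marks or coverslip
artifacts. Passing them demonstrates that the geometry is exact, the gates
compose correctly, and the pipeline is deterministic — not that the default
HSV thresholds are optimal for any particular scanner's output.

`make_concave_case()` reconstructs the failure case that motivates IoT over
point-probing heuristics: a disc with an off-center notch and a tile
placement whose four corners and four edge midpoints all lie inside the
region while the tile is not contained (IoT ≈ 0.92). An eight-point
containment test extracts it as "fully inside"; the IoT gate keeps it at
`iot_thresh` 0.5 and correctly drops it at 1.0.

## Reporting

`preview_overlay()` renders a thumbnail with annotation contours and every
grid tile outlined, color-coded by decision (extracted blue, geometry-
rejected red, background-rejected orange, sampled-out grey). It reads
decisions from the manifest rather than recomputing them, so a preview can
never disagree with the extraction it depicts. `timing_summary()` reduces
per-slide wall-clock seconds to min / max / mean / sd / variance /
quartiles (linear interpolation) / total.

## Problem sizes and limitations

The packaged fixtures use 2048 × 2048 canvases with 512 px tiles (16 grid
tiles, 3 pyramid levels) — large enough that every score value in
{0, 0.25, 0.5, 1} × {blank, mixed, solid} occurs, small enough that the
full preset ladder re-extracts in seconds; oracle cross-checks run at
g = 2048 over 200 random shapes. Slides are held in memory by the reader,
which is sized for this scale and for moderate real slides, not for
40x gigapixel scans; the `open_slide()`/`read_region()` contract is
deliberately thin so a memory-mapped or OpenSlide-backed reader could be
swapped in without touching the scoring or extraction code. Physical-unit
(micron) coordinate transforms, stain normalization, overlapping/strided
tiling, and mask co-extraction are out of scope.
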