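---
title: "Vector-assisted region proposals for barcode decoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector-assisted region proposals for barcode decoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varp)
```

## The problem

Herbarium digitization stations produce very high resolution captures
(commonly over 24 megapixels) of full specimen sheets. Each sheet carries a
small 1-D barcode — Code 39 or Code 128 — encoding the catalog number that
the image file should be named after. Conventional line scanning evaluates
every row and column of the raster for bar/space patterns, which is slow at
this resolution and fails outright whenever the barcode does not lie along a
single row or column: line scanning is rotationally variant. Downscaling the
image first is not an option, because the barcode occupies such a small
fraction of the frame that resampling destroys the narrow modules.

This package implements a region-proposal strategy around that problem.
Barcodes are, geometrically, clusters of solid rectangles. The pipeline:

1. **Contour proposals.** Binarize the grayscale image, trace the contours
   of dark connected components, and keep the rectangle-like ones. Contour
   detection does not care about orientation, which is where the rotational
   invariance of the whole method comes from.
2. **Scan vectors.** For each accepted rectangle, emit one scan vector
   through the rectangle centroid, perpendicular to its long edges. A bar's
   perpendicular crosses the entire bar pattern. Vectors are extended
   symmetrically to a length set by the image's smaller dimension (one sixth
   of it on each side of the centroid) so that wherever the originating bar
   sits inside the barcode, the vector still spans the full symbol.
3. **Composite.** Pixels under each vector are sampled (8-connected
   Bresenham traversal) and the scanlines are stacked as the columns of one
   small composite image — width = number of vectors, height = longest
   scanline, shorter columns padded white. For a 4000 × 6000 source and 200
   proposals, the composite is 200 × 1333 pixels: a 98.9% reduction in the
   pixels that the decoder must touch.
4. **Column-wise line scanning.** Each composite column is thresholded,
   run-length encoded, and passed to in-package Code 128 and Code 39
   decoders in both scan directions. If nothing decodes, a schedule of
   contrast/brightness enhancements is applied to the original composite
   and the scan repeated.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `extension_fraction` | 1/6 | Scan-vector extension per side, as a fraction of `min(height, width)`. Total sample count is `floor(2 × fraction × smaller_dim)` (1333 for a 4000-px smaller dimension). Raise it for layouts where the barcode is relatively wide (bryophyte packets, fungus labels), or set `extension_px` directly. |
| `min_rect_area_frac`, `max_rect_area_frac` | 5e-6, 1e-2 | Contour area bounds relative to image area. The floor clears speck noise (120 px² at 24 Mpx); the ceiling rejects the sheet and mounting card. |
| `approx_epsilon_frac` | 0.02 | Douglas–Peucker tolerance as a fraction of contour perimeter for the quadrilateral test. See below for why it is deliberately small. |
| `binarization` | `"otsu"` | Global Otsu threshold on dark foreground; `"adaptive"` (mean filter, block 51, offset 10) for unevenly lit sheets. |
| fallback schedule | (1.0, 0) … (3.0, 60) | Contrast gain and brightness offset steps, each applied to the *original* composite, never cumulatively, so every attempt is bounded and reproducible. |
| `min_value_length` | 4 | Decodes shorter than this are discarded as spurious; catalog numbers are longer. |
| `code39_checksum` | off | Most herbarium Code 39 labels omit the optional mod-43 check character. |

## Design choices in the rectangle filter

The filter must be **permissive**: a false positive costs one extra composite
column (a few hundred bytes of scanning); a false negative can lose the
barcode. Three choices follow from studying how rasterization treats thin
bars:

* **Epsilon 0.02, not larger.** A wide Code 39 bar at module width 2 is a
  6 × 80 px rectangle. Douglas–Peucker retains its corners only while the
  corner-to-diagonal deviation (`w·h/√(w²+h²) ≈ w` for thin bars) exceeds
  epsilon; at 0.04 × perimeter the corners collapse and every narrow-module
  bar vanishes from the proposal set.
* **Approximate the convex hull, not the raw boundary.** The pixel chain of
  a rotated rectangle is a staircase; simplifying it directly sprouts
  spurious vertices. The hull removes the concave jitter, and nearly
  collinear hull vertices (rasterization chamfers) are pruned before the
  vertex count is tested.
* **A hull-fill rescue for rounded caps.** Anti-aliased resampling of a
  rotated narrow bar rounds its end caps over most of the bar width, and no
  fixed-epsilon vertex count survives that. A contour whose convex hull
  fills at least 0.85 of its minimum-area rectangle is accepted as
  rectangle-like even when the polygon approximation does not yield exactly
  four vertices. This admits no ellipses (a hull-fill of π/4 ≈ 0.785) and
  no triangles (0.5); the separate ≥ 0.8 fill-ratio test against the
  component's own pixel count stands in all cases.

Duplicate proposals are deliberately not merged: they are harmless, and
merging heuristics add failure modes.

## Decoding choices

The decoders are implemented in the package rather than delegated to an
external barcode library: column-only (single-axis) scanning of a composite
is not something stock libraries expose, and an in-package decoder makes the
whole pipeline property-testable (`decode(render(encode(s))) == s` across
payloads, symbologies, and module widths).

* **Per-scanline thresholding.** Each composite column may come from a
  differently lit region, so binarization uses the midpoint of that column's
  own min and max intensity. A column with less than 16 gray levels of
  spread is flat — undecodable rather than erroneous — which is exactly the
  case the contrast/brightness fallback loop exists for.
* **Edge-to-edge classification for Code 128.** Runs are normalized to the
  11-module symbol width, but the primary statistic matched against the
  symbol table is the set of adjacent-run sums (leading-edge-to-leading-edge
  distances). Displacing one edge adds +δ to one run and −δ to its
  neighbour, so their sum is invariant — and edge displacement is the
  dominant error once a scan vector crosses a narrow-module barcode
  diagonally (at 45°, a 2-px module spans ~1.4 raster cells). Raw run widths
  act only as a tie-break. Within the valid symbol table the pair sums are
  unambiguous, because confusable alternatives would need an odd change in
  total bar modules, and Code 128's bar-module total is always even. The
  mandatory mod-103 checksum rejects residual misreads.
* **Wide/narrow split for Code 39.** Each 9-element group has exactly three
  wide elements, so the group's own widths are split at the gap between the
  three largest and six smallest, requiring at least 1.5:1 separation
  (nominal is 3:1; imaging jitter erodes it).
* **Both directions, every column.** Reversed runs are re-parsed with the
  same forward grammar, which is how a barcode printed in the opposite
  reading direction appears to the scanner.

## The synthetic specimen generator

No external test images ship with the package; the generator produces
specimen-like rasters with exact ground truth. What it emulates: full-sheet
captures (default 4000 × 6000), a light sheet (mean intensity 245), one
barcode at arbitrary in-plane rotation and small relative size (module
widths 2–5 px, 80 px bar height ≈ an 8–10 mm barcode at full-sheet capture
resolution), catalog-number-shaped payloads (4 letters + 8 digits),
gray rectangle and ellipse distractors standing in for labels, rulers and
plant fragments, mild Gaussian blur (σ 0.5 px) then noise (σ 5 gray levels)
applied after rotation so bar edges degrade the way optics degrade them.

What it does **not** emulate: real paper texture, pressed-plant clutter
touching the barcode, JPEG artifacts, perspective or lens distortion, uneven
illumination, damaged or partially occluded labels. Passing the synthetic
benchmark therefore demonstrates the geometric and decoding machinery —
rotational invariance, resolution reduction, symbology correctness — not
performance on any particular collection's imagery. Distractors never
overlap the barcode: the false-positive tolerance of the rectangle filter is
exercised through distractor-induced extra vectors, not occlusion.

Rendering is bit-deterministic given the spec's seed; corpora derive
per-item seeds from the master seed with a Lehmer step, so a corpus is
reproducible and order-stable regardless of how many items are rendered.

## Numerical and degenerate-input conventions

* Intensities are 8-bit throughout; 16-bit TIFF input is right-shifted.
  RGB collapses by BT.601 luma with round-half-away-from-zero.
* Coordinates are `(x, y)` with the origin at the top-left pixel center,
  x rightward, y downward; endpoints stay real-valued until rasterization.
* The nominal sample count `floor(2 × extension_fraction × smaller_dim)`
  is achieved by placing endpoints at centroid ± (n−1)/2 and traversing
  inclusively; clipping at image borders shortens vectors (never an error).
* A degenerate rectangle (zero-length edge) is skipped with a warning; an
  empty proposal set short-circuits to "no barcode found" without building
  a composite; a flat scanline yields an empty run-length encoding.
* Composite padding is white (255) because a quiet zone is white: padding
  can terminate a symbol but never fabricate one.
* Benchmark timing is reported but is never a correctness criterion —
  it is hardware-dependent by nature.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at the generator's native
4000 × 6000 size for the 100-image benchmark (expected ≥ 95 decoded, median
resolution reduction ≥ 0.95), 24 rotations of a noise-free 2000 × 3000
specimen for the rotational-invariance sweep, 500 payloads per symbology for
the encode/decode round trip, and 200 perturbed messages for checksum
soundness. Unit tests use 1000–2000 px canvases, chosen so that scan
vectors comfortably out-span the rendered barcode (the same geometric
constraint a practitioner must respect when shrinking `extension_fraction`).

## Known limitations

* Sub-pixel edge estimation is out of scope; at module width 2 and
  45° incidence a module spans ~1.4 raster cells and decoding leans on the
  edge-sum statistic and on multiple columns crossing the same barcode.
* Positional information is discarded: decoded values are not mapped back
  to source-image coordinates (the composite's column-to-vector table is
  retained in debug output, so the extension is feasible).
* Only Code 39 and Code 128 are supported; EAN/UPC, Interleaved 2-of-5 and
  2-D symbologies are non-goals.
* The whole-image baselines (`baseline_rotate_retry`,
  `baseline_upscale_retry`) exist to demonstrate strategy differences using
  the same decoder backend, not as production decoders.
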