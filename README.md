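# varp

**Vector-assisted region proposals for decoding barcodes in specimen images.**

Herbarium digitization workflows name each specimen image after the catalog
number encoded in a small 1-D barcode (Code 39 or Code 128) photographed
with the sheet. Reading that barcode from a 24-megapixel capture is a poor
fit for conventional line scanning: evaluating every row and column is slow,
and line scanning fails outright when the barcode is rotated off-axis —
while downscaling first destroys the narrow modules, because the barcode is
tiny relative to the frame.

`varp` takes a region-proposal approach built on the geometry of barcodes
(clusters of solid rectangles):

1. **Detect rectangle-like contours** in the binarized grayscale image —
   orientation-independent, hence rotationally invariant.
2. **Propose one scan vector per rectangle**, perpendicular to its long
   edges through its centroid, extended on each side by
   `extension_fraction` (default 1/6) of the image's smaller dimension, so
   a vector rooted in any bar spans the whole symbol.
3. **Build a composite image**: pixels under each vector (8-connected
   Bresenham traversal) become one column; width = number of vectors,
   height = longest scanline. For a 4000 × 6000 image with 200 proposals
   the composite is 200 × 1333 px — a 98.9% pixel reduction.
4. **Line scan the composite column-wise** with in-package Code 128
   (mod-103 checksum, code sets A/B/C, edge-to-edge classification) and
   Code 39 decoders, both scan directions, with a contrast/brightness
   fallback schedule for faint composites.

The package also ships a synthetic specimen-image generator with exact
ground truth (payload, symbology, rotation, bounding box), a benchmark
harness with rotate-retry and upscale-retry baselines, and a CLI for batch
decoding, renaming, corpus generation, and benchmarking.

## Worked example

Generate a specimen-like image (2000 × 3000 px sheet, one Code 128 barcode
at 137°, mild noise and blur, distractor shapes) and decode it:

```r
library(varp)

spec <- synthetic_spec("UCHT00123456", "code128", image_size = c(2000, 3000),
                       module_width = 3, rotation_deg = 137, seed = 42)
res <- render_specimen(spec)
out <- varp_decode(res$image)
print(out)
#> <varp_result: 23 vector(s), 1 decode(s), 99.8% reduction>
#>          value symbology checksum_ok column direction
#> 1 UCHT00123456   code128        TRUE      5   forward
```

23 rectangle-like contours were proposed (barcode bars plus a few
distractors), the 23 × 666 composite replaced 6 million source pixels
(99.8% reduction), and column 5 decoded to the ground-truth catalog number
with a valid checksum, despite the 137° rotation.

Batch decoding from the shell, validating against a collection's
catalog-number format and renaming files to the decoded value:

```sh
exec/varp decode --pattern '^UCHT[0-9]{8}$' --rename photos/*.png
exec/varp synth  --n 25 --seed 7 --out corpus/
exec/varp bench  --dir corpus/ --pattern '^[A-Z]{4}[0-9]{8}$' --out results.csv
```

`decode` prints one JSON line per file (`{file, values, n_vectors,
reduction, elapsed}`) and exits 0 when every file yielded an accepted value,
2 when any yielded none, 1 on I/O errors.

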