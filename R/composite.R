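#' Sample pixel intensities along a line segment
#'
#' Traverses the raster cells from `round(p0)` to `round(p1)` under
#' 8-connected Bresenham rasterization and returns their intensities in
#' order. No intensity interpolation is performed: the code is carried by
#' bar-width ratios, which nearest-cell sampling preserves (off-angle
#' vectors stretch all widths by the same secant factor).
#'
#' @param image A [gray_image].
#' @param p0,p1 Numeric `(x, y)` endpoints, already clipped to image bounds
#'   (clipping is the caller's contract; out-of-bounds endpoints are an
#'   error).
#' @return Numeric vector of intensities, one per traversed cell.
#' @export
sample_line <- function(image, p0, p1) {
  stopifnot(inherits(image, "gray_image"))
  if (isTRUE(all(round(p0) == round(p1))))
    stop("sample_line: p0 and p1 rasterize to the same cell")
  for (p in list(p0, p1)) {
    if (round(p[1]) < 0 || round(p[1]) > image$width - 1 ||
        round(p[2]) < 0 || round(p[2]) > image$height - 1)
      stop("sample_line: endpoint (", p[1], ", ", p[2], ") outside image bounds")
  }
  sample_bresenham_cpp(image$pixels, p0[1], p0[2], p1[1], p1[2])
}

#' Build the composite image from proposal vectors
#'
#' Samples every vector with [sample_line()] and stacks the scanlines as
#' columns: the composite has one column per vector and height equal to the
#' longest scanline. Shorter columns are padded at the bottom with 255
#' (white) -- a barcode's quiet zone is white, so padding can only terminate
#' a symbol, never fabricate one.
#'
#' @param image A [gray_image].
#' @param vectors List of `proposal_vector`s.
#' @return A `composite_image` (fields `pixels`, `width`, `height`,
#'   `column_sources`), or `NULL` when `vectors` is empty -- the distinct
#'   "no proposals" signal that lets callers report "no barcode found"
#'   without scanning anything.
#' @export
build_composite <- function(image, vectors) {
  stopifnot(inherits(image, "gray_image"))
  if (!length(vectors)) return(NULL)
  cols <- lapply(vectors, function(v) sample_line(image, v$p0, v$p1))
  hgt <- max(lengths(cols))
  px <- matrix(255, nrow = hgt, ncol = length(cols))
  for (i in seq_along(cols)) px[seq_along(cols[[i]]), i] <- cols[[i]]
  structure(list(pixels = px, width = length(cols), height = hgt,
                 column_sources = vectors),
            class = "composite_image")
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf("<composite_image %d columns x %d px>\n", x$width, x$height))
  invisible(x)
}

#' Resolution reduction achieved by compositing
#'
#' @param image The source [gray_image].
#' @param comp The [build_composite()] result.
#' @return `1 - composite_pixels / source_pixels`, in `[0, 1)`; e.g. a
#'   200 x 1333 composite of a 4000 x 6000 source gives 0.9889 (98.9%).
#' @export
resolution_reduction <- function(image, comp) {
  stopifnot(inherits(image, "gray_image"), inherits(comp, "composite_image"))
  1 - (comp$width * comp$height) / (image$width * image$height)
}

#' Write a composite as PNG with a sidecar JSON of column sources
#'
#' Debug output: the PNG shows the stacked scanlines; the JSON records each
#' column's originating vector endpoints.
#'
#' @param comp A `composite_image`.
#' @param path Output PNG path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_composite_debug <- function(comp, path) {
  stopifnot(inherits(comp, "composite_image"))
  png::writePNG(comp$pixels / 255, path)
  src <- lapply(comp$column_sources, function(v)
    list(p0 = as.numeric(v$p0), p1 = as.numeric(v$p1),
         length_px = v$length_px))
  jsonlite::write_json(src, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
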