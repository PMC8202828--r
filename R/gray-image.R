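#' Grayscale working image
#'
#' All processing in this package operates on a single 8-bit grayscale
#' raster. `gray_image()` wraps an intensity matrix (row index = y increasing
#' downward, column index = x increasing rightward, values in 0..255) in a
#' lightweight S3 container recording its height and width.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @return An object of class `gray_image` with fields `pixels`, `height`,
#'   `width`.
#' @examples
#' img <- gray_image(matrix(255, 10, 20))
#' img$height  # 10
#' img$width   # 20
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("zero-area image: height and width must both be >= 1")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("pixel intensities must lie in [0, 255]")
  # double storage: the compiled samplers take numeric matrices, and an
  # integer raster would be re-coerced (full copy) on every call
  if (is.integer(pixels)) storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, mean intensity %.1f>\n",
              x$height, x$width, mean(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) c(x$height, x$width)

# ITU-R BT.601 luma with round-half-away-from-zero (floor(x + 0.5) on the
# non-negative 8-bit scale), matching the dominant imaging-library convention.
luma_bt601 <- function(r, g, b) {
  floor(0.299 * r + 0.587 * g + 0.114 * b + 0.5)
}

#' Read an image file as an 8-bit grayscale raster
#'
#' Reads a JPEG, PNG, or TIFF file and normalizes it to the grayscale working
#' representation. RGB inputs are converted by BT.601 luma weighting
#' (0.299 R + 0.587 G + 0.114 B, rounded half away from zero); single-channel
#' 8-bit inputs pass through unchanged; 16-bit TIFF inputs are rescaled to
#' 8-bit by right shift. JPEG EXIF orientation tags are honored before
#' conversion, so the raster reflects the physical layout of the specimen.
#'
#' @param path Path to a JPEG, PNG, or TIFF file.
#' @return A [gray_image].
#' @export
load_grayscale <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path) * 255,
      jpg  = ,
      jpeg = jpeg::readJPEG(path) * 255,
      tif  = ,
      tiff = read_tiff_8bit(path),
      stop("unsupported image format '", ext, "': ", path)
    ),
    error = function(e) stop("cannot decode image: ", path, " (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  mat <- collapse_to_gray(arr)
  if (ext %in% c("jpg", "jpeg")) {
    o <- read_exif_orientation(path)
    if (!is.na(o)) mat <- apply_exif_orientation(mat, o)
  }
  gray_image(mat)
}

read_tiff_8bit <- function(path) {
  v <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(v, "bits.per.sample")
  if (!is.null(bits) && any(bits > 8)) v <- v %/% 256L
  attributes(v) <- list(dim = dim(v))  # drop TIFF metadata attributes
  storage.mode(v) <- "double"
  v
}

collapse_to_gray <- function(arr) {
  if (is.matrix(arr)) return(round(arr))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 1L) return(round(arr[, , 1]))
    if (nch >= 3L)  # alpha, if present, is ignored
      return(luma_bt601(arr[, , 1], arr[, , 2], arr[, , 3]))
    if (nch == 2L)  # gray + alpha
      return(round(arr[, , 1]))
  }
  stop("unsupported channel layout")
}

#' Write a grayscale raster as PNG
#'
#' Lossless 8-bit output; `load_grayscale(save_grayscale(img, p))` round-trips
#' bit-identically.
#'
#' @param img A [gray_image].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
save_grayscale <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

# Minimal EXIF orientation reader: scans JPEG APP1 segments for the Exif TIFF
# header and returns tag 0x0112 (1..8), or NA when absent. Digitization-station
# cameras routinely set this tag, and contour geometry must see the physical
# layout.
read_exif_orientation <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  soi <- readBin(con, "raw", 2)
  if (length(soi) < 2 || soi[1] != as.raw(0xFF) || soi[2] != as.raw(0xD8)) return(NA_integer_)
  repeat {
    marker <- readBin(con, "raw", 2)
    if (length(marker) < 2 || marker[1] != as.raw(0xFF)) return(NA_integer_)
    m <- as.integer(marker[2])
    if (m == 0xDA || m == 0xD9) return(NA_integer_)  # start of scan / EOI
    len <- readBin(con, "integer", 1, size = 2, endian = "big", signed = FALSE)
    if (length(len) < 1 || len < 2) return(NA_integer_)
    seg <- readBin(con, "raw", len - 2)
    if (m == 0xE1 && length(seg) >= 14 &&
        identical(seg[1:6], as.raw(c(0x45, 0x78, 0x69, 0x66, 0x00, 0x00)))) {
      return(parse_tiff_orientation(seg[-(1:6)]))
    }
  }
}

parse_tiff_orientation <- function(tif) {
  if (length(tif) < 8) return(NA_integer_)
  le <- identical(tif[1:2], as.raw(c(0x49, 0x49)))
  rd16 <- function(off) {
    b <- as.integer(tif[off + 1:2])
    if (le) b[1] + 256L * b[2] else b[2] + 256L * b[1]
  }
  rd32 <- function(off) {
    b <- as.integer(tif[off + 1:4])
    if (le) sum(b * c(1, 256, 65536, 16777216)) else sum(rev(b) * c(1, 256, 65536, 16777216))
  }
  ifd <- rd32(4)
  if (ifd + 2 > length(tif)) return(NA_integer_)
  n <- rd16(ifd)
  for (i in seq_len(n)) {
    ent <- ifd + 2 + 12 * (i - 1)
    if (ent + 12 > length(tif)) return(NA_integer_)
    if (rd16(ent) == 0x0112) {
      o <- rd16(ent + 8)
      if (o >= 1 && o <= 8) return(as.integer(o))
      return(NA_integer_)
    }
  }
  NA_integer_
}

# Orientation values follow the EXIF standard (1 = as stored, 3 = 180deg,
# 6 = 90deg CW, 8 = 90deg CCW, 2/4/5/7 mirrored variants).
apply_exif_orientation <- function(mat, o) {
  fliph <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  flipv <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  rot90cw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  switch(o,
    mat,                    # 1
    fliph(mat),             # 2
    flipv(fliph(mat)),      # 3
    flipv(mat),             # 4
    t(mat),                 # 5
    rot90cw(mat),           # 6
    flipv(fliph(t(mat))),   # 7
    flipv(t(mat))           # 8
  )
}
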