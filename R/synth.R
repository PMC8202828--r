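#' Specification of a synthetic specimen image
#'
#' Describes one specimen-like test image with known ground truth: a large
#' white-ish sheet (mean intensity 245) carrying one barcode at arbitrary
#' in-plane rotation, plus gray distractor rectangles and ellipses standing
#' in for labels, rulers, and plant material. Noise and blur are applied
#' after rotation so bar edges degrade the way optics degrade them.
#'
#' @param value Barcode payload.
#' @param symbology `"code128"` or `"code39"`.
#' @param image_size `(height, width)` in px; default 4000 x 6000, a typical
#'   full-sheet capture.
#' @param module_width Narrow-module width, px.
#' @param bar_height Bar height, px.
#' @param rotation_deg In-plane rotation of the barcode in `[0, 360)`;
#'   positive angles turn the long axis from +x toward +y (y grows
#'   downward).
#' @param position `(x, y)` of the barcode center, or `NULL` to place it
#'   uniformly at random wherever the rotated patch fits.
#' @param noise_sigma Gaussian intensity noise sd (8-bit units).
#' @param blur_sigma Gaussian blur sd, px.
#' @param n_distractors Number of distractor shapes.
#' @param seed Integer seed; rendering is bit-deterministic given the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(value, symbology = c("code128", "code39"),
                           image_size = c(4000, 6000), module_width = 3,
                           bar_height = 80, rotation_deg = 0,
                           position = NULL, noise_sigma = 5,
                           blur_sigma = 0.5, n_distractors = 8, seed = 1L) {
  symbology <- match.arg(symbology)
  encode_modules(value, symbology)  # validates the payload alphabet
  stopifnot(length(image_size) == 2, all(image_size >= 1),
            module_width >= 1, bar_height >= 1,
            rotation_deg >= 0, rotation_deg < 360, noise_sigma >= 0,
            blur_sigma >= 0, n_distractors >= 0)
  structure(list(value = value, symbology = symbology,
                 image_size = as.integer(image_size),
                 module_width = module_width, bar_height = bar_height,
                 rotation_deg = rotation_deg, position = position,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Rotate a grayscale matrix about its center, expanding the canvas; positive
# angle turns +x toward +y (y downward). EBImage works in (dim1, dim2) =
# (our y, our x) order, which mirrors the rotation sense, hence the sign flip.
rotate_matrix <- function(mat, deg, bg = 255, bilinear = TRUE) {
  if (deg %% 360 == 0) return(mat)
  out <- EBImage::rotate(mat, -deg, filter = if (bilinear) "bilinear" else "none",
                         bg.col = bg)
  pmin(pmax(as.matrix(out), 0), 255)
}

#' Rotate a grayscale image about its center
#'
#' Canvas expands to fit; new area is filled white. Positive angles turn the
#' +x axis toward +y (downward), i.e. a horizontal edge at orientation 0
#' acquires orientation `deg` (mod 180).
#'
#' @param image A [gray_image].
#' @param deg Rotation angle, degrees.
#' @return A [gray_image].
#' @export
rotate_gray <- function(image, deg) {
  stopifnot(inherits(image, "gray_image"))
  gray_image(round(rotate_matrix(image$pixels, deg)))
}

#' Render a synthetic specimen image
#'
#' Deterministic for a fixed spec: the barcode patch is rendered, rotated
#' with bilinear resampling, and min-composited onto the background (so bars
#' stay dark and the sheet stays light); distractors are placed without
#' touching the barcode's bounding box; blur, then Gaussian noise, are
#' applied last.
#'
#' @param spec A [synthetic_spec].
#' @return A list with `image` (a [gray_image]) and `truth` (fields `value`,
#'   `symbology`, `rotation_deg`, `bbox` -- the 4 corners of the rendered
#'   barcode in image `(x, y)` coordinates).
#' @export
render_specimen <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed %% 2147483647L)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  patch <- render_barcode_patch(spec$value, spec$symbology,
                                spec$module_width, spec$bar_height)
  rp <- rotate_matrix(patch, spec$rotation_deg)
  rh <- nrow(rp); rw <- ncol(rp)
  if (rh > H || rw > W)
    stop("barcode does not fit: rotated patch is ", rh, "x", rw,
         " px in a ", H, "x", W, " image")
  pos <- spec$position
  if (is.null(pos)) {
    pos <- c(stats::runif(1, rw / 2, W - rw / 2),
             stats::runif(1, rh / 2, H - rh / 2))
  }
  ox <- round(pos[1] - rw / 2); oy <- round(pos[2] - rh / 2)
  if (ox < 0 || oy < 0 || ox + rw > W || oy + rh > H)
    stop("barcode does not fit at position (", pos[1], ", ", pos[2], ")")

  bg <- matrix(245, H, W)
  ys <- (oy + 1):(oy + rh); xs <- (ox + 1):(ox + rw)
  bg[ys, xs] <- pmin(bg[ys, xs], rp)

  # barcode bounding box: patch corners rotated about the patch center
  th <- spec$rotation_deg * pi / 180
  hw <- ncol(patch) / 2; hh <- nrow(patch) / 2
  rel <- rbind(c(-hw, -hh), c(hw, -hh), c(hw, hh), c(-hw, hh))
  rot <- cbind(rel[, 1] * cos(th) - rel[, 2] * sin(th),
               rel[, 1] * sin(th) + rel[, 2] * cos(th))
  bbox <- sweep(rot, 2, c(ox + rw / 2, oy + rh / 2), `+`)
  colnames(bbox) <- c("x", "y")

  guard <- 10
  avoid <- c(min(bbox[, 1]) - guard, max(bbox[, 1]) + guard,
             min(bbox[, 2]) - guard, max(bbox[, 2]) + guard)
  bg <- draw_distractors(bg, spec$n_distractors, avoid)

  if (spec$blur_sigma > 0) bg <- gaussian_blur_cpp(bg, spec$blur_sigma)
  if (spec$noise_sigma > 0)
    bg <- bg + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
  img <- gray_image(round(pmin(pmax(bg, 0), 255)))
  list(image = img,
       truth = list(value = spec$value, symbology = spec$symbology,
                    rotation_deg = spec$rotation_deg, bbox = bbox))
}

# gray rectangles and ellipses emulating labels, rulers, color targets;
# rejection-sampled so they never touch the barcode area
draw_distractors <- function(bg, n, avoid) {
  H <- nrow(bg); W <- ncol(bg)
  smaller <- min(H, W)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 50L * max(n, 1L)) {
    tries <- tries + 1L
    dw <- round(stats::runif(1, 0.01, 0.08) * smaller)
    dh <- round(stats::runif(1, 0.01, 0.08) * smaller)
    cx <- stats::runif(1, dw / 2 + 1, W - dw / 2 - 1)
    cy <- stats::runif(1, dh / 2 + 1, H - dh / 2 - 1)
    shade <- stats::runif(1, 60, 180)
    shape <- sample(c("rect", "ellipse"), 1)
    x1 <- cx - dw / 2; x2 <- cx + dw / 2
    y1 <- cy - dh / 2; y2 <- cy + dh / 2
    if (x2 >= avoid[1] && x1 <= avoid[2] && y2 >= avoid[3] && y1 <= avoid[4])
      next
    xs <- max(1, round(x1)):min(W, round(x2))
    ys <- max(1, round(y1)):min(H, round(y2))
    if (shape == "rect") {
      bg[ys, xs] <- shade
    } else {
      m <- outer(((ys - cy) / (dh / 2))^2, ((xs - cx) / (dw / 2))^2, `+`) <= 1
      sub <- bg[ys, xs, drop = FALSE]
      sub[m] <- shade
      bg[ys, xs] <- sub
    }
    placed <- placed + 1L
  }
  bg
}

#' Default corpus parameter profile
#'
#' The ranges a seed-fixed corpus is drawn from: full-sheet 4000 x 6000
#' images, rotation uniform on `[0, 360)`, module widths 2-5 px, both
#' symbologies, catalog-number-shaped payloads (4 letters + 8 digits), mild
#' noise and blur, 8 distractors.
#'
#' @param image_size,module_widths,symbologies,bar_height,noise_sigma,blur_sigma,n_distractors
#'   Override individual ranges.
#' @param rotation_range Interval rotations are drawn uniformly from,
#'   degrees.
#' @return A named list.
#' @export
corpus_profile <- function(image_size = c(4000, 6000), module_widths = 2:5,
                           symbologies = c("code128", "code39"),
                           bar_height = 80, noise_sigma = 5,
                           blur_sigma = 0.5, n_distractors = 8,
                           rotation_range = c(0, 360)) {
  list(image_size = image_size, module_widths = module_widths,
       symbologies = symbologies, bar_height = bar_height,
       noise_sigma = noise_sigma, blur_sigma = blur_sigma,
       n_distractors = n_distractors, rotation_range = rotation_range)
}

# deterministic per-item seed stream (Lehmer step keeps values < 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed %% 2147483647L) * 48271 + i * 16807) %% 2147483647)
}

#' Generate a deterministic corpus of synthetic specimen specs
#'
#' Draws `n` specimen specifications from the profile's parameter ranges
#' using a counter-based seed derivation, so the corpus is deterministic and
#' order-stable regardless of how many items are later rendered. Images are
#' rendered on demand with [render_specimen()] (a rendered 24-megapixel
#' corpus would not fit in memory).
#'
#' @param n Number of specimens.
#' @param seed Integer master seed.
#' @param profile A [corpus_profile()].
#' @return A list of class `varp_corpus`; each element has `spec` (a
#'   [synthetic_spec]), plus `value`, `symbology`, `rotation_deg`,
#'   `module_width`, and `seed` for quick inspection.
#' @export
make_corpus <- function(n, seed = 1L, profile = corpus_profile()) {
  stopifnot(n >= 1)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    value <- paste0(paste(sample(LETTERS, 4, replace = TRUE), collapse = ""),
                    sprintf("%08d", sample.int(100000000L, 1) - 1L))
    pick <- function(x) if (length(x) == 1L) x else sample(x, 1)
    symbology <- pick(profile$symbologies)
    mw <- pick(profile$module_widths)
    rot <- stats::runif(1, profile$rotation_range[1],
                        profile$rotation_range[2]) %% 360
    spec <- synthetic_spec(value, symbology, image_size = profile$image_size,
                           module_width = mw, bar_height = profile$bar_height,
                           rotation_deg = rot, position = NULL,
                           noise_sigma = profile$noise_sigma,
                           blur_sigma = profile$blur_sigma,
                           n_distractors = profile$n_distractors, seed = si)
    items[[i]] <- list(spec = spec, value = value, symbology = symbology,
                       rotation_deg = rot, module_width = mw, seed = si)
  }
  structure(items, class = "varp_corpus")
}

#' Write a corpus to disk as PNGs with a CSV manifest
#'
#' @param corpus A [make_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "varp_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    it <- corpus[[i]]
    fn <- sprintf("specimen_%04d.png", i)
    res <- render_specimen(it$spec)
    save_grayscale(res$image, file.path(dir, fn))
    rows[[i]] <- data.frame(filename = fn, value = it$value,
                            symbology = it$symbology,
                            rotation_deg = it$rotation_deg,
                            module_width = it$module_width, seed = it$seed,
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
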