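# Shared fixtures, all built in code at test time.

# white 1000x1000 image with 5 disjoint solid black 8x60 vertical bars
# (60 px tall along y, 8 px wide along x); returns image + the bar placements
bars_image <- function() {
  m <- matrix(255, 1000, 1000)
  at <- list(c(100, 100), c(300, 500), c(500, 200), c(700, 800), c(850, 400))
  for (p in at) m[p[1]:(p[1] + 59), p[2]:(p[2] + 7)] <- 0
  list(image = gray_image(m), at = at)
}

# independent reference rasterization: 8-connected Bresenham in plain R,
# written from the textbook integer-error formulation
bresenham_ref <- function(x0, y0, x1, y1) {
  x0 <- round(x0); y0 <- round(y0); x1 <- round(x1); y1 <- round(y1)
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1 else -1
  sy <- if (y0 < y1) 1 else -1
  err <- dx - dy
  out <- matrix(NA_real_, max(dx, dy) + 1, 2)
  x <- x0; y <- y0
  for (i in seq_len(nrow(out))) {
    out[i, ] <- c(x, y)
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  out
}

# hand-built proposal vector (build_composite only needs the endpoints)
mk_vector <- function(p0, p1) {
  structure(list(p0 = p0, p1 = p1, source_rect = NULL,
                 length_px = sqrt(sum((p1 - p0)^2))),
            class = "proposal_vector")
}

# scanline with quiet zones for a rendered payload
render_scanline <- function(value, symbology, module_width, quiet_px = 30) {
  runs <- encode_modules(value, symbology)
  c(rep(255, quiet_px), varp:::runs_to_scanline(runs, module_width),
    rep(255, quiet_px))
}

random_payload <- function(nletters, ndigits) {
  paste0(paste(sample(LETTERS, nletters, replace = TRUE), collapse = ""),
         paste(sample(0:9, ndigits, replace = TRUE), collapse = ""))
}

# small, fast specimen spec for end-to-end unit tests; 1600x2000 keeps the
# scan vectors (533 samples) comfortably longer than the rendered barcode
small_spec <- function(value = "UCHT00123456", symbology = "code128",
                       rotation_deg = 0, seed = 7, noise_sigma = 4,
                       blur_sigma = 0.4, n_distractors = 4,
                       module_width = 3) {
  synthetic_spec(value, symbology, image_size = c(1600, 2000),
                 module_width = module_width, bar_height = 60,
                 rotation_deg = rotation_deg, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma, n_distractors = n_distractors,
                 seed = seed)
}
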