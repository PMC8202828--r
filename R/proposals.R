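#' Configuration for rectangle detection and vector proposal
#'
#' @param extension_fraction Fraction of the image's smaller dimension by
#'   which a proposal vector extends on each side of the rectangle centroid
#'   (the `--extension_value` knob). Default 1/6: the total scan length is
#'   `floor(2 * extension_fraction * min(height, width))` pixels, chosen for
#'   typical vascular-plant specimen layouts where the barcode occupies a
#'   small fraction of the frame.
#' @param min_rect_area_frac,max_rect_area_frac Admissible contour area as a
#'   fraction of the image area. The defaults admit individual barcode bars
#'   through whole label blocks while rejecting speck noise and the sheet
#'   itself.
#' @param approx_epsilon_frac Douglas-Peucker tolerance as a fraction of the
#'   contour perimeter used when testing whether a contour is a quadrilateral.
#'   Default 0.02; small enough that thin high-aspect bars (a wide Code 39
#'   bar is ~3 modules wide but tens of modules tall) retain their four
#'   corners instead of collapsing onto their long axis.
#' @param binarization `"otsu"` (global Otsu threshold, default) or
#'   `"adaptive"` (mean filter, block 51, offset 10 on the 8-bit scale) for
#'   extracting dark foreground before contour tracing.
#' @param extension_px Optional absolute override: total scan length in
#'   pixels, replacing the relative rule (useful when the barcode occupies a
#'   large fraction of the frame, as in bryophyte packet or fungus label
#'   images).
#' @return A list of class `proposal_config`.
#' @export
proposal_config <- function(extension_fraction = 1 / 6,
                            min_rect_area_frac = 5e-6,
                            max_rect_area_frac = 1e-2,
                            approx_epsilon_frac = 0.02,
                            binarization = c("otsu", "adaptive"),
                            extension_px = NULL) {
  binarization <- match.arg(binarization)
  if (!is.numeric(extension_fraction) || extension_fraction <= 0 ||
      extension_fraction > 0.5)
    stop("extension_fraction must be in (0, 0.5]")
  if (min_rect_area_frac < 0 || min_rect_area_frac >= max_rect_area_frac ||
      max_rect_area_frac > 1)
    stop("need 0 <= min_rect_area_frac < max_rect_area_frac <= 1")
  if (approx_epsilon_frac <= 0 || approx_epsilon_frac > 0.2)
    stop("approx_epsilon_frac must be in (0, 0.2]")
  if (!is.null(extension_px) && (!is.numeric(extension_px) || extension_px < 2))
    stop("extension_px must be >= 2")
  structure(list(extension_fraction = extension_fraction,
                 min_rect_area_frac = min_rect_area_frac,
                 max_rect_area_frac = max_rect_area_frac,
                 approx_epsilon_frac = approx_epsilon_frac,
                 binarization = binarization,
                 extension_px = extension_px),
            class = "proposal_config")
}

# Dark-foreground binary mask. Bars are dark on a light sheet, so foreground
# is pixels below threshold.
binarize_image <- function(img, config) {
  px <- img$pixels
  if (config$binarization == "otsu") {
    # threshold estimated on a 2x2-subsampled copy: Otsu only needs the
    # intensity histogram, and 1/4 of 24 Mpx estimates it to well under a
    # gray level
    sub <- if (length(px) > 4e6)
      px[seq(1, nrow(px), 2), seq(1, ncol(px), 2)] else px
    thr <- 255 * EBImage::otsu(EBImage::Image(sub / 255))
    px < thr
  } else {
    inv <- (255 - px) / 255
    EBImage::thresh(inv, w = 25, h = 25, offset = 10 / 255) > 0
  }
}

#' Detect rectangle-shaped contours
#'
#' Binarizes the image, labels connected dark components, and keeps those
#' whose traced boundary approximates to a convex quadrilateral, whose area
#' is an admissible fraction of the image area, and which fill at least 80%
#' of their minimum-area bounding rectangle. Survivors are reported via that
#' bounding rectangle. The filter is deliberately permissive: an incidental
#' false positive only adds one harmless column to the composite, while a
#' miss can lose the barcode. Detection is invariant to image rotation up to
#' rasterization effects.
#'
#' @param image A [gray_image].
#' @param config A [proposal_config].
#' @return A list of `rect_contour` objects, each with fields `corners`
#'   (4x2 matrix of (x, y), ordered around the rectangle), `center`, `area`,
#'   `long_edge_len`, `short_edge_len`, and `orientation_deg` (angle of the
#'   long edge in `[0, 180)`).
#' @export
detect_rectangles <- function(image, config = proposal_config()) {
  stopifnot(inherits(image, "gray_image"), inherits(config, "proposal_config"))
  mask <- binarize_image(image, config)
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask)
  npx <- tabulate(lab)
  img_area <- image$height * image$width
  keep <- which(npx >= config$min_rect_area_frac * img_area &
                npx <= config$max_rect_area_frac * img_area)
  if (!length(keep)) return(list())
  # relabel so only candidate components are traced
  lab2 <- match(lab, keep)
  lab2[is.na(lab2)] <- 0L
  dim(lab2) <- dim(lab)
  contours <- EBImage::ocontour(lab2)

  out <- list()
  for (i in seq_along(contours)) {
    oc <- contours[[i]]
    if (is.null(oc) || nrow(oc) < 4) next
    pts <- cbind(x = oc[, 2], y = oc[, 1])  # ocontour is (row, col) 0-based
    # approximate the convex hull of the boundary, not the raw pixel chain:
    # rasterization staircase would otherwise sprout spurious vertices
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    perim <- polygon_perimeter(hull)
    eps <- config$approx_epsilon_frac * perim
    approx <- prune_collinear(approx_poly_dp(hull, eps), eps)
    mar <- min_area_rect(pts)
    if (mar$area <= 0) next
    # quadrilateral test, with a rescue for rounded corners: narrow bars
    # imaged off-axis get end caps rounded over most of their width, which
    # defeats any fixed-epsilon vertex count; a convex hull that fills the
    # minimum-area rectangle is still unambiguously rectangle-like
    # (an ellipse fills only pi/4 of it)
    is_quad <- nrow(approx) == 4 && is_convex_quad(approx)
    hull_fill <- polygon_area(hull) / mar$area
    if (!is_quad && hull_fill < 0.85) next
    if (npx[keep[i]] / mar$area < 0.8) next
    out[[length(out) + 1L]] <- rect_contour(mar)
  }
  out
}

rect_contour <- function(mar) {
  long <- max(mar$extent)
  short <- min(mar$extent)
  ang <- if (mar$extent[1] >= mar$extent[2]) mar$angle else mar$angle + 90
  structure(list(corners = mar$corners,
                 center = mar$center,
                 area = mar$area,
                 long_edge_len = long,
                 short_edge_len = short,
                 orientation_deg = ang %% 180),
            class = "rect_contour")
}

#' @export
print.rect_contour <- function(x, ...) {
  cat(sprintf("<rect_contour %.0fx%.0f px at (%.0f, %.0f), %.1f deg>\n",
              x$long_edge_len, x$short_edge_len, x$center[1], x$center[2],
              x$orientation_deg))
  invisible(x)
}

# shoelace area of an ordered polygon, plus half the perimeter to count the
# pixel footprint of the boundary cells themselves
polygon_area <- function(pts) {
  nxt <- pts[c(2:nrow(pts), 1), , drop = FALSE]
  abs(sum(pts[, 1] * nxt[, 2] - nxt[, 1] * pts[, 2])) / 2 +
    polygon_perimeter(pts) / 2
}

polygon_perimeter <- function(pts) {
  d <- pts - pts[c(2:nrow(pts), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Douglas-Peucker for a closed polygon: split at the two mutually farthest
# boundary points (found on the convex hull), simplify each open chain, and
# rejoin. Returns the retained vertices in order.
approx_poly_dp <- function(pts, eps) {
  n <- nrow(pts)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (length(h) < 2) return(pts[1, , drop = FALSE])
  dm <- as.matrix(stats::dist(hp))
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  i <- h[ij[1]]; j <- h[ij[2]]
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  chain1 <- pts[i:j, , drop = FALSE]
  chain2 <- pts[c(j:n, 1:i), , drop = FALSE]
  k1 <- dp_open(chain1, eps)
  k2 <- dp_open(chain2, eps)
  # chains share endpoints; drop the duplicated ones when joining
  rbind(k1, k2[-c(1, nrow(k2)), , drop = FALSE])
}

# iterative Douglas-Peucker on an open polyline; returns retained points
dp_open <- function(pts, eps) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    if (b - a < 2) next
    idx <- (a + 1):(b - 1)
    d <- point_line_dist(pts[idx, , drop = FALSE], pts[a, ], pts[b, ])
    m <- which.max(d)
    if (d[m] > eps) {
      mi <- idx[m]
      keep[mi] <- TRUE
      stack[[length(stack) + 1L]] <- c(a, mi)
      stack[[length(stack) + 1L]] <- c(mi, b)
    }
  }
  pts[keep, , drop = FALSE]
}

# Remove nearly collinear vertices: anti-aliased rasterization chamfers the
# corners of rotated rectangles, and the chamfer vertices lie almost on the
# line joining their neighbours while true corners do not. Iteratively drops
# the vertex with the smallest such deviation while it is below eps.
prune_collinear <- function(poly, eps) {
  while (nrow(poly) > 3) {
    n <- nrow(poly)
    d <- vapply(seq_len(n), function(i) {
      a <- poly[if (i == 1) n else i - 1, ]
      b <- poly[if (i == n) 1 else i + 1, ]
      point_line_dist(poly[i, , drop = FALSE], a, b)
    }, 0)
    m <- which.min(d)
    if (d[m] >= eps) break
    poly <- poly[-m, , drop = FALSE]
  }
  poly
}

point_line_dist <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len < 1e-12) return(sqrt(rowSums(sweep(p, 2, a)^2)))
  abs((p[, 1] - a[1]) * ab[2] - (p[, 2] - a[2]) * ab[1]) / len
}

is_convex_quad <- function(q) {
  cr <- numeric(4)
  for (k in 1:4) {
    a <- q[k, ]; b <- q[k %% 4 + 1, ]; c <- q[(k + 1) %% 4 + 1, ]
    cr[k] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(cr >= 0) || all(cr <= 0)
}

# Minimum-area enclosing rectangle by rotating calipers over the convex hull.
# Extents get +1 px so they measure pixel footprint, not center-to-center
# span. Angle is the direction of the first extent axis, in degrees.
min_area_rect <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1) {
    return(list(center = hp[1, ], extent = c(1, 1), angle = 0, area = 1,
                corners = matrix(rep(hp[1, ], 4), 4, 2, byrow = TRUE)))
  }
  best <- NULL
  for (k in seq_len(m)) {
    e <- unname(hp[k %% m + 1, ] - hp[k, ])
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hp %*% u
    pv <- hp %*% v
    w <- diff(range(pu)) + 1
    hgt <- diff(range(pv)) + 1
    if (is.null(best) || w * hgt < best$area) {
      cu <- mean(range(pu)); cv <- mean(range(pv))
      ctr <- cu * u + cv * v
      hw <- w / 2; hh <- hgt / 2
      corners <- rbind(ctr + hw * u + hh * v, ctr - hw * u + hh * v,
                       ctr - hw * u - hh * v, ctr + hw * u - hh * v)
      colnames(corners) <- c("x", "y")
      best <- list(center = as.numeric(ctr), extent = c(w, hgt),
                   angle = (atan2(u[2], u[1]) * 180 / pi) %% 180,
                   area = w * hgt, corners = corners)
    }
  }
  best
}

# Nominal scan length in samples: a function of the image's smaller dimension
# only, never of rectangle size, so behaviour is stable across resolutions.
nominal_vector_samples <- function(image, config) {
  if (!is.null(config$extension_px)) return(as.integer(config$extension_px))
  floor(2 * config$extension_fraction * min(image$height, image$width))
}

#' Propose a scan vector for one rectangle
#'
#' The vector runs perpendicular to the rectangle's long edges (through the
#' midpoints of the two opposite long edges), so that for a barcode bar it
#' crosses the full bar pattern. It is centered on the rectangle centroid,
#' extended symmetrically to the nominal scan length, then clipped to image
#' bounds.
#'
#' @param rect A `rect_contour`.
#' @param image The source [gray_image].
#' @param config A [proposal_config].
#' @return A `proposal_vector` (fields `p0`, `p1`, `source_rect`,
#'   `length_px`), or `NULL` with a warning for a degenerate rectangle.
#' @export
vector_from_rect <- function(rect, image, config = proposal_config()) {
  stopifnot(inherits(rect, "rect_contour"))
  if (rect$short_edge_len < 1e-6 || rect$long_edge_len < 1e-6) {
    warning("skipping degenerate rectangle (zero-length edge)")
    return(NULL)
  }
  n <- nominal_vector_samples(image, config)
  ang <- (rect$orientation_deg + 90) * pi / 180
  u <- c(cos(ang), sin(ang))
  half <- (n - 1) / 2
  p0 <- rect$center - half * u
  p1 <- rect$center + half * u
  seg <- clip_segment(p0, p1, image$width, image$height)
  if (is.null(seg)) return(NULL)
  structure(list(p0 = seg$p0, p1 = seg$p1, source_rect = rect,
                 length_px = sqrt(sum((seg$p1 - seg$p0)^2))),
            class = "proposal_vector")
}

# Liang-Barsky clip of segment p0-p1 to the pixel-center rectangle
# [0, w-1] x [0, h-1]; NULL when wholly outside.
clip_segment <- function(p0, p1, w, h) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- 0; hi <- if (k == 1) w - 1 else h - 1
    if (abs(d[k]) < 1e-12) {
      if (p0[k] < lo || p0[k] > hi) return(NULL)
    } else {
      ta <- (lo - p0[k]) / d[k]
      tb <- (hi - p0[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  list(p0 = p0 + t0 * d, p1 = p0 + t1 * d)
}

#' Propose scan vectors for a whole image
#'
#' Runs [detect_rectangles()] and maps [vector_from_rect()] over the result,
#' dropping degenerate rectangles. Order is deterministic: sorted by
#' rectangle centroid y, then x.
#'
#' @inheritParams detect_rectangles
#' @return List of `proposal_vector`s (possibly empty).
#' @export
propose_vectors <- function(image, config = proposal_config()) {
  rects <- detect_rectangles(image, config)
  if (!length(rects)) return(list())
  ord <- order(vapply(rects, function(r) r$center[2], 0),
               vapply(rects, function(r) r$center[1], 0))
  vecs <- lapply(rects[ord], vector_from_rect, image = image, config = config)
  vecs[!vapply(vecs, is.null, TRUE)]
}
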