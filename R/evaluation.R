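#' Did decoding succeed for a collection's catalog-number format?
#'
#' A decode attempt counts as a success when at least one decoded value
#' fully matches the collection-specific regular expression; extraneous
#' decodes (rulers, secondary labels) are ignored.
#'
#' @param decoded Data frame of decoded barcodes ([decode_composite()] /
#'   `varp_decode()$decoded`).
#' @param pattern An anchored regular expression for the catalog-number
#'   format, validated at configuration time via [validate_pattern()].
#' @return Logical.
#' @export
is_success <- function(decoded, pattern) {
  if (is.null(decoded) || !nrow(decoded)) return(FALSE)
  any(grepl(paste0("^(?:", pattern, ")$"), decoded$value, perl = TRUE))
}

#' Validate a catalog-number regular expression
#'
#' @param pattern Regular expression.
#' @return `pattern`, invisibly; error if the expression does not compile.
#' @export
validate_pattern <- function(pattern) {
  ok <- tryCatch({ grepl(pattern, "x", perl = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("invalid regular expression: ", pattern)
  invisible(pattern)
}

# ---------------------------------------------------------------- baselines

# Scan raw image rows and columns through the line-scan decoders: the
# traditional, rotationally variant strategy. stride > 1 subsamples the
# scanlines for speed.
scan_rows_and_columns <- function(image, decoder = decoder_config(),
                                  stride = 1L) {
  px <- image$pixels
  hits <- list()
  for (i in seq(1, nrow(px), by = stride)) {
    rec <- decode_scanline(px[i, ], decoder)
    if (nrow(rec)) hits[[length(hits) + 1L]] <- rec
  }
  for (j in seq(1, ncol(px), by = stride)) {
    rec <- decode_scanline(px[, j], decoder)
    if (nrow(rec)) hits[[length(hits) + 1L]] <- rec
  }
  if (!length(hits)) return(empty_decoded())
  res <- do.call(rbind, hits)
  res[!duplicated(res[, c("value", "symbology")]), , drop = FALSE]
}

#' Single-pass row/column line scan (no retries)
#'
#' The plain line-scanning strategy: every row and every column of the raw
#' image is scanned once. Fails whenever the barcode does not lie along a
#' single row or column.
#'
#' @param image A [gray_image].
#' @param decoder A [decoder_config].
#' @param stride Scanline subsampling step.
#' @return Data frame of decoded barcodes.
#' @export
baseline_linescan <- function(image, decoder = decoder_config(), stride = 1L) {
  stopifnot(inherits(image, "gray_image"))
  scan_rows_and_columns(image, decoder, stride)
}

#' Rotate-retry baseline
#'
#' Reactive strategy: line scan the full-scale image, and on failure rotate
#' it and rescan, stepping through `angles` until a decode or exhaustion.
#' 15-degree steps bring any orientation within the decoder's angular
#' tolerance.
#'
#' @inheritParams baseline_linescan
#' @param angles Rotation angles to try, degrees.
#' @return Data frame of decoded barcodes (possibly empty).
#' @export
baseline_rotate_retry <- function(image, decoder = decoder_config(),
                                  angles = seq(0, 345, by = 15),
                                  stride = 1L) {
  stopifnot(inherits(image, "gray_image"))
  for (a in angles) {
    im <- if (a == 0) image else rotate_gray(image, a)
    res <- scan_rows_and_columns(im, decoder, stride)
    if (nrow(res)) return(res)
  }
  empty_decoded()
}

#' Upscale-retry baseline
#'
#' Reactive strategy: line scan, and on failure upscale the image and
#' rescan. Helps when modules are too narrow for the scanner, but cannot
#' overcome rotation.
#'
#' @inheritParams baseline_linescan
#' @param scales Scale factors to try, in order.
#' @return Data frame of decoded barcodes (possibly empty).
#' @export
baseline_upscale_retry <- function(image, decoder = decoder_config(),
                                   scales = c(1, 1.25, 1.5, 2),
                                   stride = 1L) {
  stopifnot(inherits(image, "gray_image"))
  for (s in scales) {
    im <- if (s == 1) image else {
      up <- EBImage::resize(image$pixels, w = round(nrow(image$pixels) * s))
      gray_image(round(pmin(pmax(as.matrix(up), 0), 255)))
    }
    res <- scan_rows_and_columns(im, decoder, stride)
    if (nrow(res)) return(res)
  }
  empty_decoded()
}

# ---------------------------------------------------------------- benchmark

#' Benchmark decoding methods over a corpus
#'
#' For every image and method: `repeats` timed runs (image loading included,
#' when the corpus holds file paths), with the per-image time taken as the
#' median of the repeats and method order randomized per image from `seed`.
#' Success is judged by [is_success()] against `pattern`. A method that
#' errors on an image is logged as a failure for that image; the run never
#' aborts.
#'
#' @param corpus Either a `varp_corpus` (items rendered on demand) or a
#'   character vector of image paths.
#' @param methods Named list of functions taking one corpus entry (a
#'   [gray_image] or a path) and returning a decoded data frame or a
#'   `varp_result`.
#' @param pattern Catalog-number regular expression for [is_success()].
#' @param repeats Timed repeats per image/method (default 5).
#' @param seed Seed for the per-image method-order randomization.
#' @return Data frame, one row per method: `method`, `n_images`,
#'   `n_success`, `success_rate`, `median_time_success_s`,
#'   `median_time_failure_s`, `median_time_combined_s`, `median_reduction`
#'   (NA for methods that do not report a composite reduction). The
#'   per-image log is attached as attribute `"log"`.
#' @export
run_benchmark <- function(corpus, methods, pattern, repeats = 5L, seed = 1L) {
  validate_pattern(pattern)
  stopifnot(length(methods) >= 1, !is.null(names(methods)),
            all(nzchar(names(methods))), repeats >= 1)
  n <- length(corpus)
  stopifnot(n >= 1)
  set.seed(seed)
  log <- list()
  for (i in seq_len(n)) {
    entry <- if (inherits(corpus, "varp_corpus")) {
      render_specimen(corpus[[i]]$spec)$image
    } else corpus[[i]]
    for (m in sample(names(methods))) {
      times <- numeric(repeats)
      res <- NULL
      for (r in seq_len(repeats)) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(methods[[m]](entry), error = function(e) e)
        times[r] <- proc.time()[["elapsed"]] - t0
      }
      failed_hard <- inherits(res, "error")
      decoded <- if (failed_hard) empty_decoded()
                 else if (inherits(res, "varp_result")) res$decoded
                 else res
      reduction <- if (inherits(res, "varp_result")) res$reduction else NA_real_
      log[[length(log) + 1L]] <- data.frame(
        image = i, method = m, success = is_success(decoded, pattern),
        time_s = stats::median(times), reduction = reduction,
        error = failed_hard, stringsAsFactors = FALSE)
    }
  }
  log <- do.call(rbind, log)
  out <- lapply(split(log, log$method), function(d) {
    data.frame(
      method = d$method[1], n_images = nrow(d), n_success = sum(d$success),
      success_rate = mean(d$success),
      median_time_success_s = safe_median(d$time_s[d$success]),
      median_time_failure_s = safe_median(d$time_s[!d$success]),
      median_time_combined_s = stats::median(d$time_s),
      median_reduction = safe_median(d$reduction[!is.na(d$reduction)]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

safe_median <- function(x) if (length(x)) stats::median(x) else NA_real_

#' Write benchmark results and the per-image log
#'
#' Results go to CSV (one row per method); the per-image log to JSON-lines.
#'
#' @param results A [run_benchmark()] result.
#' @param csv_path Output CSV path.
#' @param log_path Optional JSON-lines path for the per-image log.
#' @return `csv_path`, invisibly.
#' @export
write_benchmark <- function(results, csv_path, log_path = NULL) {
  utils::write.csv(results, csv_path, row.names = FALSE)
  if (!is.null(log_path)) {
    log <- attr(results, "log")
    con <- file(log_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(log)))
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
  }
  invisible(csv_path)
}
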