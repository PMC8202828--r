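#' Decoder configuration
#'
#' @param symbologies Character vector of symbologies to attempt, in order.
#' @param code39_checksum Verify the optional Code 39 mod-43 checksum and
#'   strip the check character? Off by default: most herbarium Code 39
#'   labels omit it.
#' @param fallback_schedule List of `c(gain, offset)` contrast/brightness
#'   steps tried in order when the initial scan decodes nothing. Each step is
#'   applied to the original composite (`pixel' = clip(gain * pixel +
#'   offset)`), not cumulatively, so every attempt's distortion is bounded
#'   and reproducible. The first step is the identity (the initial scan).
#' @param min_value_length Decoded values shorter than this are discarded as
#'   spurious; catalog numbers are always longer.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(symbologies = c("code128", "code39"),
                           code39_checksum = FALSE,
                           fallback_schedule = list(c(1.0, 0), c(1.3, 10),
                                                    c(1.6, 20), c(2.0, 40),
                                                    c(3.0, 60)),
                           min_value_length = 4L) {
  symbologies <- match.arg(symbologies, c("code128", "code39"),
                           several.ok = TRUE)
  stopifnot(all(vapply(fallback_schedule, length, 0L) == 2L),
            all(vapply(fallback_schedule, function(s) s[1] >= 1, TRUE)),
            min_value_length >= 1)
  structure(list(symbologies = symbologies,
                 code39_checksum = isTRUE(code39_checksum),
                 fallback_schedule = fallback_schedule,
                 min_value_length = as.integer(min_value_length)),
            class = "decoder_config")
}

#' Binarize a scanline into bar/space run lengths
#'
#' Thresholds at the midpoint of the scanline's min and max intensity --
#' per-scanline rather than global, because each composite column may come
#' from a differently lit region of the source -- and run-length encodes the
#' result. Leading/trailing light runs are retained as quiet zones. A flat
#' scanline (max - min < 16) is undecodable and yields an empty encoding.
#'
#' @param values Numeric intensity sequence (length >= 1).
#' @return A list with `lengths` (integer run lengths) and `is_bar` (logical,
#'   `TRUE` for dark runs), alternating.
#' @export
binarize_scanline <- function(values) {
  stopifnot(length(values) >= 1)
  lo <- min(values); hi <- max(values)
  if (hi - lo < 16) return(list(lengths = integer(0), is_bar = logical(0)))
  r <- rle(values < (lo + hi) / 2)
  list(lengths = r$lengths, is_bar = r$values)
}

reverse_runs <- function(runs) {
  list(lengths = rev(runs$lengths), is_bar = rev(runs$is_bar))
}

decoded_record <- function(value, symbology, checksum_ok, column = NA_integer_,
                           direction = "forward") {
  data.frame(value = value, symbology = symbology, checksum_ok = checksum_ok,
             column = column, direction = direction,
             stringsAsFactors = FALSE)
}

empty_decoded <- function() {
  data.frame(value = character(0), symbology = character(0),
             checksum_ok = logical(0), column = integer(0),
             direction = character(0), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------- Code 128

# classify 6 run widths against the symbol table after normalizing to 11
# modules. The primary statistic is edge-to-edge: sums of adjacent runs,
# which cancel the displacement of their shared edge (the dominant error
# once runs are quantized to raster cells); raw widths act as tie-break.
# Returns the best value (0-based) or NA if no pattern is close.
classify_code128 <- function(w) {
  total <- sum(w)
  if (total <= 0) return(NA_integer_)
  n <- w * 11 / total
  e <- n[1:5] + n[2:6]
  de <- colSums(abs(t(CODE128_EDGE_SUMS) - e))
  dw <- colSums(abs(t(CODE128_WIDTHS) - n))
  score <- de + 0.25 * dw
  best <- which.min(score)
  if (de[best] > 2.2 || dw[best] > 3.5) return(NA_integer_)
  best - 1L
}

matches_code128_stop <- function(w) {
  total <- sum(w)
  if (total <= 0) return(FALSE)
  n <- w * 13 / total
  sum(abs(n[1:6] + n[2:7] - (CODE128_STOP[1:6] + CODE128_STOP[2:7]))) < 2.6 &&
    sum(abs(n - CODE128_STOP)) < 3.5
}

#' Decode a Code 128 barcode from run lengths
#'
#' Slides over the run-length encoding looking for a start pattern (code set
#' A, B, or C), classifies each subsequent 11-module symbol against the
#' 107-pattern table, and requires a valid stop pattern and mod-103 checksum
#' (`(start + sum(i * value_i)) mod 103` must equal the penultimate symbol).
#' Code-set switching, the shift code, and the digit-pair set C are
#' supported. Both scan directions are attempted.
#'
#' @param runs Output of [binarize_scanline()].
#' @return A one-row data frame (`value`, `symbology`, `checksum_ok`,
#'   `column`, `direction`) or `NULL` when nothing decodes.
#' @export
decode_code128 <- function(runs) {
  for (dir in c("forward", "reverse")) {
    r <- if (dir == "forward") runs else reverse_runs(runs)
    v <- decode_code128_forward(r)
    if (!is.null(v)) {
      v$direction <- dir
      return(v)
    }
  }
  NULL
}

decode_code128_forward <- function(runs) {
  L <- runs$lengths
  B <- runs$is_bar
  n <- length(L)
  if (n < 13) return(NULL)  # start + check + stop at minimum
  for (s in which(B)) {
    if (s + 5 > n) break
    w <- L[s:(s + 5)]
    start <- classify_code128(w)
    if (is.na(start) || start < 103L) next
    module <- sum(w) / 11
    if (s > 1 && L[s - 1] < 5 * module) next  # leading quiet zone
    vals <- start
    pos <- s + 6
    ok <- FALSE
    while (pos + 6 <= n + 1) {
      if (pos + 6 <= n && matches_code128_stop(L[pos:(pos + 6)])) {
        # trailing quiet zone: end of scan or a wide space after the stop bar
        after <- pos + 7
        if (after > n || L[after] >= 3 * sum(L[pos:(pos + 6)]) / 13)
          ok <- TRUE
        break
      }
      sym <- classify_code128(L[pos:(pos + 5)])
      if (is.na(sym)) break
      vals <- c(vals, sym)
      pos <- pos + 6
    }
    if (!ok || length(vals) < 3) next
    k <- length(vals)
    cs <- (vals[1] + sum(seq_len(k - 2) * vals[2:(k - 1)])) %% 103
    if (cs != vals[k]) next
    text <- translate_code128(vals[1], vals[2:(k - 1)])
    if (is.null(text) || !nzchar(text)) next
    return(decoded_record(text, "code128", TRUE))
  }
  NULL
}

translate_code128 <- function(start, data) {
  set <- switch(as.character(start), "103" = "A", "104" = "B", "105" = "C")
  out <- character(0)
  shift <- NULL
  for (v in data) {
    cur <- if (is.null(shift)) set else shift
    shift <- NULL
    if (cur == "C") {
      if (v <= 99L) out <- c(out, sprintf("%02d", v))
      else if (v == CODE128_CODE_TO_B) set <- "B"
      else if (v == CODE128_CODE_TO_A) set <- "A"
      else return(NULL)
    } else if (cur == "B") {
      if (v <= 94L) out <- c(out, code128_b_char(v))
      else if (v == CODE128_SHIFT) shift <- "A"
      else if (v == CODE128_CODE_TO_C) set <- "C"
      else if (v == 101L) set <- "A"
      else return(NULL)
    } else {  # A
      if (v <= 95L) out <- c(out, code128_a_char(v))
      else if (v == CODE128_SHIFT) shift <- "B"
      else if (v == CODE128_CODE_TO_C) set <- "C"
      else if (v == CODE128_CODE_TO_B) set <- "B"
      else return(NULL)
    }
  }
  paste(out, collapse = "")
}

# ----------------------------------------------------------------- Code 39

# classify a 9-element group (5 bars, 4 spaces) as wide/narrow against the
# group's own widths: a valid character has exactly 3 wide elements, so the
# split is the gap between the 3 widest and the 6 narrowest, which must be a
# clean >= 1.5:1 separation (nominal is 3:1; imaging jitter erodes it)
classify_code39 <- function(w) {
  s <- sort(w)
  if (s[7] <= s[6]) return(NA_character_)       # no wide/narrow gap
  if (mean(s[7:9]) < 1.5 * mean(s[1:6])) return(NA_character_)
  thr <- (s[6] + s[7]) / 2
  pat <- paste(ifelse(w > thr, "W", "N"), collapse = "")
  hit <- names(CODE39_PATTERNS)[match(pat, CODE39_PATTERNS)]
  if (is.na(hit)) NA_character_ else hit
}

#' Decode a Code 39 barcode from run lengths
#'
#' Looks for the leading `*` delimiter, then reads 9-element groups
#' separated by single narrow inter-character gaps until the trailing `*`.
#' Wide/narrow classification is per group, against the midpoint of that
#' group's own widths. Both scan directions are attempted. The mod-43
#' checksum is verified (and the check character stripped) only when
#' `checksum = TRUE`.
#'
#' @param runs Output of [binarize_scanline()].
#' @param checksum Verify the optional mod-43 check character?
#' @return A one-row data frame or `NULL`.
#' @export
decode_code39 <- function(runs, checksum = FALSE) {
  for (dir in c("forward", "reverse")) {
    r <- if (dir == "forward") runs else reverse_runs(runs)
    v <- decode_code39_forward(r, checksum)
    if (!is.null(v)) {
      v$direction <- dir
      return(v)
    }
  }
  NULL
}

decode_code39_forward <- function(runs, checksum = FALSE) {
  L <- runs$lengths
  B <- runs$is_bar
  n <- length(L)
  if (n < 19) return(NULL)  # *, one character, * at minimum
  for (s in which(B)) {
    if (s + 8 > n) break
    g <- L[s:(s + 8)]
    if (!identical(classify_code39(g), "*")) next
    narrow <- mean(sort(g)[1:6])
    if (s > 1 && L[s - 1] < 3 * narrow) next  # leading quiet zone
    chars <- character(0)
    pos <- s + 9
    ok <- FALSE
    while (pos + 9 <= n) {
      if (B[pos] || L[pos] > 4 * narrow) break  # need a narrow gap
      g <- L[(pos + 1):(pos + 9)]
      ch <- classify_code39(g)
      if (is.na(ch)) break
      if (ch == "*") {
        after <- pos + 10
        if (after > n || L[after] >= 3 * narrow) ok <- TRUE
        break
      }
      chars <- c(chars, ch)
      pos <- pos + 10
    }
    if (!ok || !length(chars)) next
    cs_ok <- NA
    if (checksum) {
      if (length(chars) < 2) next
      vals <- match(chars, strsplit(CODE39_CHECK_ALPHABET, "")[[1]]) - 1L
      cs_ok <- sum(vals[-length(vals)]) %% 43 == vals[length(vals)]
      if (!cs_ok) next
      chars <- chars[-length(chars)]
    }
    return(decoded_record(paste(chars, collapse = ""), "code39",
                          isTRUE(cs_ok)))
  }
  NULL
}

# ------------------------------------------------------------- composite

decode_scanline <- function(values, config) {
  runs <- binarize_scanline(values)
  if (!length(runs$lengths)) return(empty_decoded())
  out <- list()
  for (sym in config$symbologies) {
    rec <- switch(sym,
                  code128 = decode_code128(runs),
                  code39 = decode_code39(runs, config$code39_checksum))
    if (!is.null(rec) && nchar(rec$value) >= config$min_value_length)
      out[[length(out) + 1L]] <- rec
  }
  if (!length(out)) empty_decoded() else do.call(rbind, out)
}

enhance_pixels <- function(px, gain, offset) {
  pmin(pmax(gain * px + offset, 0), 255)
}

#' Decode every column of a composite image
#'
#' Scans each column as a single scanline through the enabled symbology
#' decoders (columns only -- the composite's construction makes row-wise
#' scanning meaningless). If nothing decodes, each contrast/brightness step
#' of the fallback schedule is applied to the original composite in turn and
#' the scan repeated, stopping at the first step that yields a decode.
#' Results are deduplicated by (value, symbology).
#'
#' @param comp A `composite_image`, or `NULL` (the "no proposals" signal).
#' @param config A [decoder_config].
#' @return Data frame of decoded barcodes (possibly 0-row): `value`,
#'   `symbology`, `checksum_ok`, `column`, `direction`.
#' @export
decode_composite <- function(comp, config = decoder_config()) {
  if (is.null(comp)) return(empty_decoded())
  stopifnot(inherits(comp, "composite_image"))
  for (step in config$fallback_schedule) {
    px <- if (step[1] == 1 && step[2] == 0) comp$pixels
          else enhance_pixels(comp$pixels, step[1], step[2])
    hits <- list()
    for (j in seq_len(ncol(px))) {
      rec <- decode_scanline(px[, j], config)
      if (nrow(rec)) {
        rec$column <- j
        hits[[length(hits) + 1L]] <- rec
      }
    }
    if (length(hits)) {
      res <- do.call(rbind, hits)
      return(res[!duplicated(res[, c("value", "symbology")]), , drop = FALSE])
    }
  }
  empty_decoded()
}
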