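# Barcode encoders: the exact inverse of the line-scan decoders, sharing the
# same symbol tables. Used by the synthetic specimen generator and by
# round-trip property tests.

#' Encode a payload as bar/space module runs
#'
#' Code 128: start symbol (code set chosen to minimize length; digit runs
#' are packed into the two-digits-per-symbol set C), data symbols, mod-103
#' checksum symbol, stop pattern. Code 39: `*`-delimited characters with
#' single narrow inter-character gaps (wide elements are 3 modules).
#' Quiet zones are not included; the renderer adds them.
#'
#' @param value Text payload within the symbology's alphabet.
#' @param symbology `"code128"` or `"code39"`.
#' @return A list with `lengths` (module counts per run), `is_bar`, and for
#'   Code 128 also `values` (the symbol value sequence including start,
#'   checksum, but not the stop).
#' @export
encode_modules <- function(value, symbology = c("code128", "code39")) {
  symbology <- match.arg(symbology)
  if (!nzchar(value)) stop("payload must be non-empty")
  if (symbology == "code128") encode_code128_modules(value)
  else encode_code39_modules(value)
}

# choose code sets: runs of >= 4 digits (or a trailing even-length digit run
# of >= 2) go to set C, everything else to set B
code128_plan_symbols <- function(value) {
  chars <- strsplit(value, "")[[1]]
  bad <- chars[!(charToRaw(value) >= as.raw(32) & charToRaw(value) <= as.raw(126))]
  if (length(bad))
    stop("character not encodable in Code 128 set B/C: '", bad[1], "'")
  n <- length(chars)
  isdig <- chars %in% as.character(0:9)
  digrun <- integer(n)  # length of the digit run starting at each position
  run <- 0L
  for (i in n:1) {
    run <- if (isdig[i]) run + 1L else 0L
    digrun[i] <- run
  }
  syms <- integer(0)
  set <- NULL
  i <- 1L
  while (i <= n) {
    usec <- digrun[i] >= 4L || (digrun[i] >= 2L && i + digrun[i] - 1L == n)
    if (usec) {
      take <- digrun[i] - digrun[i] %% 2L
      if (is.null(set)) syms <- CODE128_START_C
      else if (set != "C") syms <- c(syms, CODE128_CODE_TO_C)
      set <- "C"
      for (k in seq(i, i + take - 1L, by = 2L))
        syms <- c(syms, as.integer(paste0(chars[k], chars[k + 1L])))
      i <- i + take
    } else {
      if (is.null(set)) syms <- CODE128_START_B
      else if (set != "B") syms <- c(syms, CODE128_CODE_TO_B)
      set <- "B"
      syms <- c(syms, code128_b_value(chars[i]))
      i <- i + 1L
    }
  }
  syms
}

encode_code128_modules <- function(value) {
  syms <- code128_plan_symbols(value)
  k <- length(syms)
  check <- (syms[1] + if (k > 1) sum(seq_len(k - 1) * syms[-1]) else 0L) %% 103L
  allsym <- c(syms, check)
  widths <- c(t(CODE128_WIDTHS[allsym + 1L, , drop = FALSE]), CODE128_STOP)
  list(lengths = as.integer(widths),
       is_bar = rep_len(c(TRUE, FALSE), length(widths)),
       values = as.integer(allsym), symbology = "code128")
}

encode_code39_modules <- function(value, wide = CODE39_WIDE_RATIO) {
  chars <- strsplit(value, "")[[1]]
  known <- names(CODE39_PATTERNS)
  bad <- setdiff(chars, setdiff(known, "*"))
  if (length(bad))
    stop("character not encodable in Code 39: '", bad[1], "'")
  lengths <- integer(0)
  is_bar <- logical(0)
  full <- c("*", chars, "*")
  for (j in seq_along(full)) {
    pat <- strsplit(CODE39_PATTERNS[[full[j]]], "")[[1]]
    lengths <- c(lengths, ifelse(pat == "W", wide, 1L))
    is_bar <- c(is_bar, rep_len(c(TRUE, FALSE), 9L))
    if (j < length(full)) {  # narrow inter-character gap
      lengths <- c(lengths, 1L)
      is_bar <- c(is_bar, FALSE)
    }
  }
  list(lengths = as.integer(lengths), is_bar = is_bar, symbology = "code39")
}

# scale module runs to pixels and expand to a 0/255 scanline (no quiet zones)
runs_to_scanline <- function(runs, module_width = 1) {
  px <- round(runs$lengths * module_width)
  rep(ifelse(runs$is_bar, 0, 255), times = px)
}

#' Render a barcode as a grayscale patch
#'
#' Black (0) bars on white (255), `quiet_modules` white modules on each side
#' (default 10, the symbology minimum), `bar_height` rows tall.
#'
#' @param value Payload text.
#' @param symbology `"code128"` or `"code39"`.
#' @param module_width Width of one module, px.
#' @param bar_height Bar height, px.
#' @param quiet_modules Quiet-zone width in modules per side.
#' @return Numeric matrix (`bar_height` x patch width) of intensities.
#' @export
render_barcode_patch <- function(value, symbology = c("code128", "code39"),
                                 module_width = 3, bar_height = 80,
                                 quiet_modules = 10) {
  symbology <- match.arg(symbology)
  runs <- encode_modules(value, symbology)
  quiet <- rep(255, round(quiet_modules * module_width))
  line <- c(quiet, runs_to_scanline(runs, module_width), quiet)
  matrix(rep(line, each = bar_height), nrow = bar_height)
}
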