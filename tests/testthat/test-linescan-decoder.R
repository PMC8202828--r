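test_that("binarize_scanline emits alternating run lengths with quiet zones", {
  r <- binarize_scanline(c(rep(255, 5), rep(0, 3), rep(255, 5)))
  expect_equal(r$lengths, c(5, 3, 5))
  expect_equal(r$is_bar, c(FALSE, TRUE, FALSE))

  expect_length(binarize_scanline(rep(255, 40))$lengths, 0)
  expect_length(binarize_scanline(rep(7, 3))$lengths, 0)
  # contrast below 16 gray levels is flat
  expect_length(binarize_scanline(c(rep(120, 5), rep(135, 5)))$lengths, 0)
  expect_gt(length(binarize_scanline(c(rep(120, 5), rep(140, 5)))$lengths), 0)
})

test_that("minimal Code 128 message decodes with correct mod-103 checksum", {
  e <- encode_modules("A", "code128")
  expect_equal(e$values, c(104L, 33L, 34L))  # (104 + 1*33) %% 103 == 34
  runs <- binarize_scanline(render_scanline("A", "code128", 3))
  rec <- decode_code128(runs)
  expect_equal(rec$value, "A")
  expect_true(rec$checksum_ok)
  expect_equal(rec$direction, "forward")
})

test_that("reversed run sequences decode to the same value, direction reverse", {
  for (sym in c("code128", "code39")) {
    sl <- render_scanline("HELLO42", sym, 2)
    fwd <- if (sym == "code128") decode_code128(binarize_scanline(sl))
           else decode_code39(binarize_scanline(sl))
    rev_ <- if (sym == "code128") decode_code128(binarize_scanline(rev(sl)))
            else decode_code39(binarize_scanline(rev(sl)))
    expect_equal(fwd$value, "HELLO42")
    expect_equal(rev_$value, "HELLO42")
    expect_equal(fwd$direction, "forward")
    expect_equal(rev_$direction, "reverse")
  }
})

test_that("single-symbol substitutions in Code 128 are rejected by checksum", {
  set.seed(21)
  for (i in 1:25) {
    value <- random_payload(3, 6)
    e <- encode_modules(value, "code128")
    k <- length(e$values)
    pos <- sample(2:(k - 1), 1)  # perturb a data or checksum symbol
    bad <- e$values
    bad[pos] <- (bad[pos] + sample(1:102, 1)) %% 103
    widths <- c(t(varp:::CODE128_WIDTHS[bad + 1L, , drop = FALSE]),
                varp:::CODE128_STOP)
    runs <- list(lengths = c(30L, as.integer(widths * 2), 30L),
                 is_bar = c(FALSE, rep_len(c(TRUE, FALSE), length(widths)), FALSE))
    expect_null(decode_code128(runs))
  }
})

test_that("round trip holds for random payloads at module widths 2-5", {
  set.seed(42)
  for (i in 1:40) {
    value <- random_payload(sample(2:8, 1), sample(2:12, 1))
    mw <- sample(2:5, 1)
    sym <- sample(c("code128", "code39"), 1)
    sl <- render_scanline(value, sym, mw)
    rec <- decode_scanline(sl, decoder_config())
    expect_true(value %in% rec$value[rec$symbology == sym],
                info = paste(sym, "mw", mw, value))
  }
})

test_that("Code 39 tolerates per-bar width jitter", {
  set.seed(5)
  runs <- encode_modules("UCHT001234", "code39")
  for (i in 1:10) {
    px <- runs$lengths * 2L
    px[px >= 6] <- 6L  # narrow 2 / wide 6
    jit <- pmax(1L, px + sample(c(-1L, 0L, 1L), length(px), replace = TRUE))
    sl <- c(rep(255, 25), rep(ifelse(runs$is_bar, 0, 255), times = jit),
            rep(255, 25))
    rec <- decode_code39(binarize_scanline(sl))
    expect_equal(rec$value, "UCHT001234")
  }
})

test_that("Code 39 requires its delimiters", {
  runs <- encode_modules("AB12", "code39")
  n <- length(runs$lengths)
  # strip the trailing "*" (last 9 elements and its gap)
  trunc <- list(lengths = c(20L, runs$lengths[1:(n - 10)] * 2L, 20L),
                is_bar = c(FALSE, runs$is_bar[1:(n - 10)], FALSE))
  expect_null(decode_code39(trunc))
})

test_that("Code 39 mod-43 checksum is verified and stripped when enabled", {
  alphabet <- strsplit(varp:::CODE39_CHECK_ALPHABET, "")[[1]]
  value <- "UCHT001234"
  vals <- match(strsplit(value, "")[[1]], alphabet) - 1L
  check <- alphabet[sum(vals) %% 43 + 1L]
  sl <- render_scanline(paste0(value, check), "code39", 2)
  rec <- decode_code39(binarize_scanline(sl), checksum = TRUE)
  expect_equal(rec$value, value)
  expect_true(rec$checksum_ok)
  wrong <- alphabet[(sum(vals) + 5) %% 43 + 1L]
  sl2 <- render_scanline(paste0(value, wrong), "code39", 2)
  expect_null(decode_code39(binarize_scanline(sl2), checksum = TRUE))
  # without checksum the same rendering decodes verbatim
  expect_equal(decode_code39(binarize_scanline(sl2))$value,
               paste0(value, wrong))
})

test_that("decode_composite scans all columns, deduplicates, falls back", {
  sl <- render_scanline("MARY00012345", "code128", 2)
  h <- length(sl)
  # two columns with the same barcode, one noise column
  px <- cbind(sl, c(rep(255, 20), rep(0, 20), rep(255, h - 40)), sl)
  comp <- structure(list(pixels = px, width = 3L, height = h,
                         column_sources = NULL), class = "composite_image")
  res <- decode_composite(comp)
  expect_equal(nrow(res), 1)
  expect_equal(res$value, "MARY00012345")

  blank <- structure(list(pixels = matrix(255, 50, 4), width = 4L,
                          height = 50L, column_sources = NULL),
                     class = "composite_image")
  expect_equal(nrow(decode_composite(blank)), 0)
})

test_that("low-contrast composites decode only after enhancement", {
  sl <- render_scanline("LOWC1234", "code128", 3)
  faint <- ifelse(sl < 128, 120, 135)  # 15 gray levels of contrast
  comp <- structure(list(pixels = cbind(faint), width = 1L,
                         height = length(faint), column_sources = NULL),
                    class = "composite_image")
  # no enhancement: flat
  plain <- decoder_config(fallback_schedule = list(c(1.0, 0)))
  expect_equal(nrow(decode_composite(comp, plain)), 0)
  # default schedule reaches a decoding step
  res <- decode_composite(comp)
  expect_equal(res$value, "LOWC1234")
})

test_that("scanning is single-axis: transposing the composite changes results", {
  sl <- render_scanline("AXIS0001", "code128", 2)
  comp <- structure(list(pixels = cbind(sl, sl), width = 2L,
                         height = length(sl), column_sources = NULL),
                    class = "composite_image")
  tcomp <- structure(list(pixels = t(cbind(sl, sl)), width = length(sl),
                          height = 2L, column_sources = NULL),
                     class = "composite_image")
  expect_equal(decode_composite(comp)$value, "AXIS0001")
  expect_equal(nrow(decode_composite(tcomp)), 0)
})

test_that("short spurious values are suppressed by min_value_length", {
  sl <- render_scanline("AB", "code128", 3)
  comp <- structure(list(pixels = cbind(sl), width = 1L, height = length(sl),
                         column_sources = NULL), class = "composite_image")
  expect_equal(nrow(decode_composite(comp)), 0)  # nchar 2 < 4
  cfg <- decoder_config(min_value_length = 2)
  expect_equal(decode_composite(comp, cfg)$value, "AB")
})
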