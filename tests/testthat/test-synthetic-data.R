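test_that("encode_modules produces the documented symbol sequences", {
  expect_equal(encode_modules("A", "code128")$values, c(104L, 33L, 34L))
  # pure digit runs pack into set C, two digits per symbol
  e <- encode_modules("1234", "code128")
  expect_equal(e$values[1:3], c(105L, 12L, 34L))
  expect_length(e$values, 4L)  # start, 2 data, check
  # mixed payload switches sets
  e2 <- encode_modules("AB123456", "code128")
  expect_equal(e2$values[1], 104L)
  expect_true(99L %in% e2$values)  # switch to C for the digit run
  expect_error(encode_modules("café", "code128"), "not encodable")
  expect_error(encode_modules("abc", "code39"), "'a'")
  expect_error(encode_modules("", "code128"), "non-empty")
})

test_that("every Code 128 symbol is 11 modules, stop is 13, patterns unique", {
  W <- varp:::CODE128_WIDTHS
  expect_equal(nrow(W), 106)  # values 0..105
  expect_true(all(rowSums(W) == 11))
  expect_false(anyDuplicated(apply(W, 1, paste, collapse = "")) > 0)
  expect_equal(sum(varp:::CODE128_STOP), 13)
  p39 <- varp:::CODE39_PATTERNS
  expect_true(all(nchar(p39) == 9))
  expect_true(all(vapply(strsplit(p39, ""),
                         function(x) sum(x == "W"), 0L) == 3L))
  expect_false(anyDuplicated(p39) > 0)
})

test_that("rendering is bit-deterministic for a fixed spec", {
  spec <- small_spec(seed = 31, rotation_deg = 33)
  a <- render_specimen(spec)
  b <- render_specimen(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("clean unrotated rendering reproduces the encoded module runs", {
  spec <- synthetic_spec("TEST00112233", "code128",
                         image_size = c(600, 900), module_width = 3,
                         bar_height = 40, rotation_deg = 0,
                         position = c(450, 300), noise_sigma = 0,
                         blur_sigma = 0, n_distractors = 0, seed = 2)
  res <- render_specimen(spec)
  # scan the row through the barcode center
  row <- res$image$pixels[300, ]
  runs <- binarize_scanline(row)
  enc <- encode_modules("TEST00112233", "code128")
  bars <- runs$lengths[runs$is_bar]
  expect_equal(bars, enc$lengths[enc$is_bar] * 3)
  expect_equal(decode_scanline(row, decoder_config())$value, "TEST00112233")
})

test_that("a barcode that cannot fit is refused, never clipped", {
  expect_error(
    render_specimen(synthetic_spec("WXYZ01234567", "code39",
                                   image_size = c(300, 400),
                                   module_width = 3, seed = 1)),
    "does not fit")
  expect_error(
    render_specimen(synthetic_spec("AB123456", "code128",
                                   image_size = c(500, 700), module_width = 2,
                                   position = c(680, 250), seed = 1)),
    "does not fit")
})

test_that("ground-truth bbox encloses exactly the dark barcode pixels", {
  spec <- small_spec(rotation_deg = 50, noise_sigma = 0, blur_sigma = 0,
                     n_distractors = 0, seed = 13)
  res <- render_specimen(spec)
  dark <- which(res$image$pixels < 128, arr.ind = TRUE)
  x <- dark[, 2] - 1; y <- dark[, 1] - 1
  bb <- res$truth$bbox
  expect_true(all(x >= min(bb[, "x"]) - 2 & x <= max(bb[, "x"]) + 2))
  expect_true(all(y >= min(bb[, "y"]) - 2 & y <= max(bb[, "y"]) + 2))
})

test_that("corpora are deterministic, order-stable, catalog-number shaped", {
  c1 <- make_corpus(10, seed = 42)
  c2 <- make_corpus(10, seed = 42)
  expect_identical(lapply(c1, `[`, c("value", "symbology", "rotation_deg")),
                   lapply(c2, `[`, c("value", "symbology", "rotation_deg")))
  vals <- vapply(c1, `[[`, "", "value")
  expect_true(all(grepl("^[A-Z]{2,5}[0-9]{6,9}$", vals)))
  expect_false(anyDuplicated(vals) > 0)
  # a larger draw covers all four rotation quadrants
  rots <- vapply(make_corpus(60, seed = 7), `[[`, 0, "rotation_deg")
  expect_setequal(unique(floor(rots / 90)), 0:3)
  # different seeds give different corpora
  c3 <- make_corpus(10, seed = 43)
  expect_false(identical(vals, vapply(c3, `[[`, "", "value")))
})

test_that("write_corpus emits loadable PNGs and a faithful manifest", {
  dir <- withr::local_tempdir()
  profile <- corpus_profile(image_size = c(500, 700), module_widths = 2,
                            symbologies = "code128", bar_height = 30,
                            noise_sigma = 3, blur_sigma = 0.3,
                            n_distractors = 2)
  corpus <- make_corpus(2, seed = 5, profile = profile)
  manifest_path <- write_corpus(corpus, dir)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  expect_equal(nrow(man), 2)
  img <- load_grayscale(file.path(dir, man$filename[1]))
  expect_equal(dim(img), c(500L, 700L))
  expect_equal(man$value[1], corpus[[1]]$value)
})

test_that("the pipeline decodes a noise-free specimen at every rotation step", {
  # rotational-invariance core claim, at unit-test scale
  for (a in c(0, 45, 110, 250)) {
    spec <- small_spec(rotation_deg = a, noise_sigma = 0, blur_sigma = 0,
                       n_distractors = 0, seed = 3)
    res <- varp_decode(render_specimen(spec)$image)
    expect_true("UCHT00123456" %in% res$decoded$value, info = paste("at", a))
  }
})
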