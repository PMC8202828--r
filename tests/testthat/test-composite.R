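test_that("sample_line matches an independent Bresenham enumeration", {
  set.seed(11)
  img <- gray_image(matrix(sample(0:255, 50 * 60, replace = TRUE), 50, 60))
  cases <- list(c(2, 7, 40, 7), c(5, 3, 5, 45), c(0, 0, 59, 49),
                c(50, 40, 3, 8), c(10.4, 20.6, 48.2, 5.1))
  for (cs in cases) {
    got <- sample_line(img, c(cs[1], cs[2]), c(cs[3], cs[4]))
    cells <- bresenham_ref(cs[1], cs[2], cs[3], cs[4])
    want <- img$pixels[cbind(cells[, 2] + 1, cells[, 1] + 1)]
    expect_identical(got, want)
  }
})

test_that("constant fields and checkerboard diagonals sample as expected", {
  img <- gray_image(matrix(50, 20, 20))
  expect_identical(sample_line(img, c(3, 5), c(13, 5)), rep(50, 11))

  chk <- gray_image(255 * ((outer(1:4, 1:4, `+`) %% 2)))
  d <- sample_line(chk, c(0, 0), c(3, 3))
  expect_length(d, 4)
  expect_true(all(d == chk$pixels[1, 1]))  # diagonal cells share one color
})

test_that("endpoint contract: out-of-bounds and degenerate segments error", {
  img <- gray_image(matrix(0, 10, 10))
  expect_error(sample_line(img, c(-2, 0), c(5, 0)), "bounds")
  expect_error(sample_line(img, c(0, 0), c(12, 0)), "bounds")
  expect_error(sample_line(img, c(3, 3), c(3.2, 3.2)), "same cell")
})

test_that("build_composite stacks columns in order with white padding", {
  set.seed(4)
  img <- gray_image(matrix(sample(0:254, 80 * 80, replace = TRUE), 80, 80))
  vecs <- list(mk_vector(c(10, 10), c(19, 10)),   # 10 samples
               mk_vector(c(5, 20), c(5, 39)),     # 20 samples
               mk_vector(c(40, 70), c(40, 41)))   # 30 samples
  comp <- build_composite(img, vecs)
  expect_equal(comp$width, 3)
  expect_equal(comp$height, 30)
  for (i in 1:3) {
    want <- sample_line(img, vecs[[i]]$p0, vecs[[i]]$p1)
    expect_identical(comp$pixels[seq_along(want), i], want)
    if (length(want) < 30)
      expect_true(all(comp$pixels[(length(want) + 1):30, i] == 255))
  }
  # single vector: composite column is exactly the scanline
  c1 <- build_composite(img, vecs[2])
  expect_identical(c1$pixels[, 1], sample_line(img, vecs[[2]]$p0, vecs[[2]]$p1))
  expect_equal(c1$width, 1)
})

test_that("empty vector list yields the distinct no-proposals signal", {
  img <- gray_image(matrix(255, 10, 10))
  expect_null(build_composite(img, list()))
  expect_equal(nrow(decode_composite(NULL)), 0)
})

test_that("permuting vectors permutes columns and leaves decodes unchanged", {
  set.seed(9)
  sl <- render_scanline("QX123456", "code128", 2)
  m <- matrix(sample(200:255, 400 * 500, replace = TRUE), 400, 500)
  m[100, 30:(29 + length(sl))] <- sl
  img <- gray_image(m)
  vecs <- list(mk_vector(c(10, 300), c(10, 360)),
               mk_vector(c(25, 99), c(389, 99)),  # crosses the barcode row? no: along row y=99
               mk_vector(c(40, 5), c(40, 80)))
  vecs[[2]] <- mk_vector(c(20, 99), c(20 + length(sl) + 15, 99))
  perm <- c(3, 1, 2)
  a <- build_composite(img, vecs)
  b <- build_composite(img, vecs[perm])
  expect_identical(a$pixels[, perm], b$pixels)
  da <- decode_composite(a)
  db <- decode_composite(b)
  expect_setequal(da$value, db$value)
})

test_that("resolution reduction follows the composite dimension arithmetic", {
  src <- gray_image(matrix(255, 40, 60))
  comp <- structure(list(pixels = matrix(255, 1333, 200), width = 200,
                         height = 1333, column_sources = NULL),
                    class = "composite_image")
  big <- gray_image(matrix(255, 4000, 6000))
  expect_equal(resolution_reduction(big, comp), 1 - 200 * 1333 / (4000 * 6000))
  expect_equal(round(100 * resolution_reduction(big, comp), 1), 98.9)

  same <- structure(list(pixels = matrix(255, 40, 60), width = 60, height = 40,
                         column_sources = NULL), class = "composite_image")
  expect_equal(resolution_reduction(src, same), 0)
})

test_that("composite pixel count is bounded by vectors times nominal length", {
  fx <- bars_image()
  cfg <- proposal_config()
  vecs <- propose_vectors(fx$image, cfg)
  comp <- build_composite(fx$image, vecs)
  expect_lte(comp$width * comp$height, length(vecs) * floor(1000 / 3))
})

test_that("debug output writes the PNG and a sidecar of column sources", {
  img <- gray_image(matrix(c(rep(0, 50), rep(255, 550)), 20, 30))
  vecs <- list(mk_vector(c(0, 5), c(29, 5)))
  comp <- build_composite(img, vecs)
  tmp <- withr::local_tempfile(fileext = ".png")
  write_composite_debug(comp, tmp)
  expect_true(file.exists(tmp))
  side <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_length(side, 1)
  expect_equal(unlist(side[[1]]$p0), c(0, 5))
})
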