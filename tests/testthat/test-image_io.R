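test_that("PNG round-trips preserve rasters and masks bit-exactly", {
  d <- withr::local_tempdir()
  px <- array(0L, dim = c(2, 2, 3))
  img <- rgb_image(px)
  write_rgb(img, file.path(d, "black.png"))
  back <- load_rgb(file.path(d, "black.png"))
  expect_true(all(back$pixels == 0L))

  set.seed(11)
  px <- array(sample(0:255, 8 * 9 * 3, replace = TRUE), dim = c(8, 9, 3))
  write_rgb(rgb_image(px), file.path(d, "rand.png"))
  expect_identical(load_rgb(file.path(d, "rand.png"))$pixels,
                   rgb_image(px)$pixels)

  for (lab in list(matrix(0L, 5, 7),
                   matrix(as.integer((row(matrix(0, 6, 6)) +
                                      col(matrix(0, 6, 6))) %% 2), 6, 6))) {
    m <- binary_mask(lab)
    write_mask(m, file.path(d, "m.png"))
    expect_identical(read_mask(file.path(d, "m.png"))$labels, m$labels)
  }
})

test_that("mask reading thresholds any nonzero value to 1", {
  d <- withr::local_tempdir()
  png::writePNG(matrix(c(0, 7, 255, 0) / 255, 2, 2), file.path(d, "g.png"))
  m <- read_mask(file.path(d, "g.png"))
  expect_identical(m$labels, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  img <- gray_image(matrix(0.5, 3, 3))
  expect_error(read_mask(file.path(d, "g.png"), companion = img),
               "shape")
})

test_that("grayscale input replicates to 3 channels; bad paths error", {
  d <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 4), file.path(d, "gray.png"))
  expect_warning(img <- load_rgb(file.path(d, "gray.png")), "replicated")
  expect_equal(dim(img$pixels), c(4L, 4L, 3L))
  expect_true(all(img$pixels == 128L))
  expect_error(load_rgb(file.path(d, "nope.png")), "cannot read")
  writeLines("not a png", file.path(d, "junk.png"))
  expect_error(load_rgb(file.path(d, "junk.png")), "unreadable")
})

test_that("16-bit samples rescale by the v/257 law", {
  # png::writePNG cannot emit 16-bit files, so the conversion applied by
  # load_rgb to a decoder-normalized 16-bit sample (v/65535 -> *255, half-up)
  # is checked against the independent divide-by-257 oracle over all values
  v <- 0:65535
  got <- floor(v / 65535 * 255 + 0.5)      # load_rgb's arithmetic
  oracle <- floor(v / 257 + 0.5)           # scale-by-257-and-round
  expect_identical(got, oracle)
})

test_that("channel extraction follows the standard color-space formulas", {
  px <- array(0L, dim = c(1, 2, 3))
  px[1, 1, ] <- c(10L, 200L, 30L)
  px[1, 2, ] <- c(255L, 0L, 0L)
  img <- rgb_image(px)
  expect_equal(extract_channel(img, "green")$intensities[1, 1], 200 / 255)
  expect_equal(extract_channel(img, "red")$intensities[1, 2], 1)
  # Y of XYZ for pure red = first entry of the matrix Y row
  expect_equal(extract_channel(img, "Y")$intensities[1, 2], 0.2126729,
               tolerance = 1e-7)
  gray <- rgb_image(array(rep(77L, 3 * 4 * 3), dim = c(3, 4, 3)))
  expect_true(all(extract_channel(gray, "S")$intensities == 0))
  expect_error(extract_channel(img, "hue"), "unknown channel")
  expect_equal(dim(extract_channel(img, "L")$intensities), c(1L, 2L))
})

test_that("min-max normalization maps affinely and is idempotent", {
  img <- gray_from(matrix(c(0.2, 0.4, 0.6), 1, 3))
  expect_equal(normalize_gray(img)$intensities, matrix(c(0, 0.5, 1), 1, 3))
  expect_warning(z <- normalize_gray(gray_from(matrix(0.3, 4, 4))), "constant")
  expect_true(all(z$intensities == 0))
  set.seed(5)
  r <- gray_from(matrix(runif(64, 0.1, 0.9), 8, 8))
  n1 <- normalize_gray(r)
  expect_equal(min(n1$intensities), 0)
  expect_equal(max(n1$intensities), 1)
  # order of pixels preserved
  expect_equal(cor(rank(r$intensities), rank(n1$intensities)), 1)
  # idempotence
  n2 <- normalize_gray(n1)
  expect_equal(n2$intensities, n1$intensities, tolerance = 1e-12)
})
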