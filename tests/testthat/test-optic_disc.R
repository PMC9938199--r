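test_that("preprocessing: median filter and Sobel behave as expected", {
  cfg <- od_config(median_kernel = 3)
  flat <- gray_from(matrix(0.5, 32, 32))
  pp <- preprocess_for_od(flat, cfg)
  expect_equal(sum(pp$edges$labels), 0)

  # single-pixel impulse removed by a 3x3 median
  imp <- matrix(0.5, 32, 32); imp[16, 16] <- 1
  pp <- preprocess_for_od(gray_from(imp), cfg)
  expect_equal(pp$smoothed$intensities, matrix(0.5, 32, 32))

  # vertical step: hand-computed Sobel magnitude 4/(4*sqrt(2)) at the two
  # columns flanking the step, zero elsewhere
  stp <- step_image(16, 16, split = 8, lo = 0, hi = 1)
  edges <- exuscan:::sobel_edges(stp$intensities, threshold = 0.1)
  expect_true(all(edges[, 8:9] == 1L))
  expect_true(all(edges[, c(1:7, 10:16)] == 0L))
  mag_hand <- 4 / (4 * sqrt(2))
  expect_gt(mag_hand, 0.1)
})

test_that("quarter candidacy sees rings, half-rings, and nothing", {
  h <- 101; w <- 101; center <- c(51, 51); rad <- 20
  dg <- dist_grid(h, w, center)
  ring <- binary_mask(matrix(as.integer(abs(dg - rad) <= 0.5), h, w),
                      "optic_disc")
  cfg <- od_config(od_radius = rad)
  q <- quarter_candidacy(ring, center, cfg)
  expect_true(all(q$quarters_ok))
  expect_true(q$candidate)

  # upper half-ring only (angles [0, pi] means rows above center, +y up)
  rows <- matrix(seq_len(h), h, w)
  half <- ring$labels; half[rows > center[1]] <- 0L
  qh <- quarter_candidacy(binary_mask(half, "optic_disc"), center, cfg)
  expect_equal(qh$quarters_ok, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(qh$candidate)

  empty <- binary_mask(matrix(0L, h, w), "optic_disc")
  expect_false(quarter_candidacy(empty, center, cfg)$candidate)
})

test_that("the brighter of two ringed circles is selected", {
  h <- 120; w <- 120; rad <- 15
  m <- matrix(0.4, h, w)
  dg1 <- dist_grid(h, w, c(40, 35))
  dg2 <- dist_grid(h, w, c(80, 85))
  m[dg1 <= rad] <- 0.8                      # bright disc
  m[dg2 <= rad] <- 0.1                      # dark but equally-ringed circle
  img <- gray_from(m)
  cfg <- od_config(od_radius = rad, median_kernel = 3)
  pp <- preprocess_for_od(img, cfg)
  res <- select_optic_disc(pp$smoothed, pp$edges, cfg)
  expect_false(is.null(res))
  expect_lt(sqrt(sum((res$center - c(40, 35))^2)), 3)
  # blank image yields no candidate
  blank <- preprocess_for_od(gray_from(matrix(0.5, 64, 64)), cfg)
  expect_null(select_optic_disc(blank$smoothed, blank$edges, cfg))
})

test_that("synthetic scenes localize to the true disc center", {
  sc <- generate_scene(scene_spec(seed = 2))
  g <- normalize_gray(extract_channel(sc$image, "green"))
  od <- locate_optic_disc(g, od_config(od_radius = sc$od_radius))
  expect_false(is.null(od$result))
  expect_lte(sqrt(sum((od$result$center - sc$od_center)^2)), 2)
  expect_true(od$result$brightest_direction_mean >= 0 &&
              od$result$brightest_direction_mean <= 1)
})

test_that("exclusion masks rasterize, dilate, and clip correctly", {
  res <- structure(list(center = c(32L, 32L), radius = 5), class = "od_result")
  cfg0 <- od_config(od_radius = 5, dilation = 0)
  m0 <- od_exclusion_mask(res, c(64, 64), cfg0)
  area <- sum(m0$labels)
  expect_gte(area, pi * 4.5^2)
  expect_lte(area, pi * 5.5^2)
  m3 <- od_exclusion_mask(res, c(64, 64), od_config(od_radius = 5, dilation = 3))
  expect_true(all(m3$labels[m0$labels == 1L] == 1L))
  expect_gt(sum(m3$labels), area)
  corner <- structure(list(center = c(1L, 1L), radius = 5), class = "od_result")
  mc <- od_exclusion_mask(corner, c(64, 64), cfg0)
  expect_lt(sum(mc$labels), area)   # clipped to bounds, no error
  # removing the exclusion never adds detections
  img <- disc_image()
  base <- detect_exudates(img)
  sub <- detect_exudates(img, exclusion = m0)
  expect_subset_mask(sub, base)
})
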