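test_that("radial differences are exact consecutive differences", {
  mk <- function(v) structure(list(values = v), class = "radial_samples")
  expect_equal(unclass(radial_differences(mk(c(0.5, 0.5, 0.5)))), c(0, 0))
  expect_equal(unclass(radial_differences(mk(c(0.9, 0.7)))), -0.2)
  expect_length(radial_differences(mk(0.3)), 0)
  set.seed(3)
  v <- runif(10)
  d <- radial_differences(mk(v))
  oracle <- vapply(2:10, function(n) v[n] - v[n - 1], numeric(1))
  expect_equal(unclass(d), oracle)
})

test_that("non-constant test requires a strict drop strictly beyond th1", {
  expect_true(is_nonconstant(c(-0.02), 0.015))
  expect_false(is_nonconstant(c(0.5, 0.2), 0.015))
  expect_false(is_nonconstant(c(-0.015), 0.015))   # boundary: strict
  expect_false(is_nonconstant(numeric(0), 0.015))
  expect_true(is_nonconstant(c(0.1, -0.5, 0.2), 0.3))
})

test_that("sector entrance counting matches a raw-trig oracle", {
  cimg <- gray_from(matrix(0.5, 64, 64))
  sc <- make_semicircles(8)[[5]]
  r <- semicircle_entrance(cimg, c(32, 32), sc)
  expect_equal(r$count, 0L)
  expect_false(r$entrance)

  # bright-side pixel 10 px from a step edge, sector facing the dark side
  img <- step_image()
  center <- c(32, 43)  # bright half, edge at col 32/33
  cfg <- detection_config()
  for (i in c(4, 5)) {   # the two sectors pointing at the dark side
    sc <- make_semicircles(8)[[i]]
    got <- semicircle_entrance(img, center, sc, cfg)
    want <- entrance_count_oracle(img, center, sc$angle_lo, sc$angle_hi)
    expect_equal(got$count, want)
    expect_true(got$entrance)
  }
  # sector 1 points away from the edge: nothing to find
  sc1 <- make_semicircles(8)[[1]]
  expect_equal(semicircle_entrance(img, center, sc1, cfg)$count,
               entrance_count_oracle(img, center, sc1$angle_lo, sc1$angle_hi))
})

test_that("the th3 rule honors comparator and consecutiveness", {
  run <- exuscan:::circular_run
  sat <- exuscan:::th3_satisfied
  flags1 <- c(TRUE, TRUE, TRUE, rep(FALSE, 5))
  expect_equal(run(flags1), 3L)
  expect_true(sat(run(flags1), detection_config(th3 = 3)))
  expect_false(sat(run(flags1),
                   detection_config(th3 = 3, comparator_th3 = "strict_greater")))
  alt <- rep(c(TRUE, FALSE), 4)
  expect_equal(run(alt), 1L)
  expect_false(sat(run(alt), detection_config(th3 = 3)))
  expect_true(sat(sum(alt), detection_config(th3 = 3)))  # non-consecutive count
  # wrap-around run and exhaustive small cases vs enumeration oracle
  expect_equal(run(c(TRUE, FALSE, FALSE, TRUE, TRUE)), 3L)
  for (k in 0:255) {
    f <- as.logical(bitwAnd(k, 2^(0:7)) > 0)
    expect_equal(run(f), circular_run_oracle(f))
  }
})

test_that("classify_pixel agrees with detect on constructed scenes", {
  img <- disc_image()
  cfg <- detection_config()
  mask <- detect_exudates(img, cfg)
  expect_gt(sum(mask$labels), 0)
  for (p in list(c(32, 32), c(32, 44), c(5, 5), c(1, 1), c(64, 64),
                 c(20, 32), c(45, 45))) {
    expect_identical(classify_pixel(img, p, cfg)$is_he,
                     mask$labels[p[1], p[2]] == 1L)
  }
  # detections confined to the disc plus a thin margin
  dg <- dist_grid(64, 64, c(32, 32))
  expect_true(all(dg[mask$labels == 1L] <= 12 + 3))
  # constant image detects nothing anywhere
  cmask <- detect_exudates(gray_from(matrix(0.42, 40, 40)), cfg)
  expect_equal(sum(cmask$labels), 0)
})

test_that("optimized and reference detectors agree bit-for-bit", {
  for (seed in 1:3) {
    img <- random_image(seed, 32, 32)
    cfg <- detection_config(r1 = 12)
    expect_identical(detect_exudates(img, cfg)$labels,
                     detect_exudates_reference(img, cfg)$labels)
  }
  # also under non-default options
  img <- random_image(9, 32, 32)
  for (cfg in list(detection_config(r1 = 12, require_consecutive = FALSE),
                   detection_config(r1 = 12, comparator_th3 = "strict_greater"),
                   detection_config(r1 = 12, n_semi = 4, n_dirs = 3, th2 = 1),
                   detection_config(r1 = 12, fill = TRUE))) {
    expect_identical(detect_exudates(img, cfg)$labels,
                     detect_exudates_reference(img, cfg)$labels)
  }
})

test_that("detection is monotone in the thresholds and radii", {
  img <- disc_image(96, 96, c(48, 48), radius = 14)
  base <- detect_exudates(img, detection_config())
  expect_subset_mask(detect_exudates(img, detection_config(th1 = 0.025)), base)
  expect_subset_mask(base, detect_exudates(img, detection_config(r1 = 40)))
  expect_subset_mask(detect_exudates(img, detection_config(r0 = 15)), base)
  expect_subset_mask(detect_exudates(img, detection_config(th3 = 5)), base)
  expect_subset_mask(
    detect_exudates(img, detection_config(th2 = 3)), base)
})

test_that("exclusion masks only remove detections", {
  img <- disc_image()
  cfg <- detection_config()
  base <- detect_exudates(img, cfg)
  excl <- binary_mask(matrix(as.integer(dist_grid(64, 64, c(32, 32)) <= 8),
                             64, 64), "optic_disc")
  sub <- detect_exudates(img, cfg, exclusion = excl)
  expect_subset_mask(sub, base)
  expect_true(all(sub$labels[excl$labels == 1L] == 0L))
  bad <- binary_mask(matrix(0L, 10, 10))
  expect_error(detect_exudates(img, cfg, exclusion = bad), "shape")
})

test_that("config invariants are enforced", {
  expect_error(detection_config(th1 = 0), "th1")
  expect_error(detection_config(th2 = 5, n_dirs = 5), "th2")
  expect_error(detection_config(th3 = 9), "th3")
  expect_error(detection_config(r0 = 10, r1 = 10), "r1")
})
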