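# Fixtures built in code; no binary files ship with the package.

gray_from <- function(m) gray_image(m, channel_tag = "synthetic")

# flat background with one bright hard-edged disc
disc_image <- function(h = 64, w = 64, center = c(32, 32), radius = 12,
                       bg = 0.4, contrast = 0.3) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(bg, h, w)
  m[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- bg + contrast
  gray_from(m)
}

# vertical step: cols <= split dark, rest bright
step_image <- function(h = 64, w = 64, split = 32, lo = 0.2, hi = 0.8) {
  m <- matrix(lo, h, w)
  m[, (split + 1):w] <- hi
  gray_from(m)
}

dist_grid <- function(h, w, center) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2)
}

random_image <- function(seed, h = 64, w = 64) {
  set.seed(seed)
  normalize_gray(gray_from(matrix(runif(h * w), h, w)))
}

# independent naive longest-circular-run (enumerates every start position)
circular_run_oracle <- function(flags) {
  n <- length(flags)
  best <- 0L
  for (s in seq_len(n)) {
    len <- 0L
    for (k in seq_len(n)) {
      if (flags[(s + k - 2L) %% n + 1L]) len <- len + 1L else break
    }
    best <- max(best, len)
  }
  best
}

# brute-force count of non-constant directions in one sector, written from
# raw trig, independent of the package's geometry helpers
entrance_count_oracle <- function(img, center, angle_lo, angle_hi,
                                  n_dirs = 5, th1 = 0.015, r0 = 4, r1 = 25) {
  m <- img$intensities
  h <- nrow(m); w <- ncol(m)
  count <- 0L
  for (j in seq_len(n_dirs)) {
    a <- angle_lo + (j - 0.5) * (angle_hi - angle_lo) / n_dirs
    prev_rc <- NULL
    vals <- c()
    for (r in seq(r0, r1, by = 1)) {
      rr <- floor(center[1] - r * sin(a) + 0.5)
      cc <- floor(center[2] + r * cos(a) + 0.5)
      if (!is.null(prev_rc) && prev_rc[1] == rr && prev_rc[2] == cc) next
      if (rr < 1 || rr > h || cc < 1 || cc > w) break
      vals <- c(vals, m[rr, cc])
      prev_rc <- c(rr, cc)
    }
    if (length(vals) >= 2) {
      df <- diff(vals)
      if (any(df < 0 & abs(df) > th1)) count <- count + 1L
    }
  }
  count
}

expect_subset_mask <- function(inner, outer) {
  expect_true(all(outer$labels[inner$labels == 1L] == 1L))
}
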