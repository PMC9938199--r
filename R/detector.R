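#' Detection parameters
#'
#' All tunables of the pixel-wise exudate detector. The defaults are the
#' reference operating point of the method: an intensity drop is significant
#' when it exceeds `th1 = 0.015` on the normalized `[0, 1]` scale; a sector
#' is an entrance area when strictly more than `th2 = 2` of its directions
#' are non-constant; a pixel is exudate when at least `th3 = 3` (circularly)
#' consecutive sectors are entrance areas; the radial search range is
#' `[r0, r1] = [4, 25]` pixels.
#'
#' @param th1 minimum significant single-step intensity drop (normalized
#'   units, strict `>`).
#' @param th2 minimum count of non-constant directions per sector
#'   (strict `>`).
#' @param th3 sector-count threshold for the pixel decision.
#' @param r0,r1 inner/outer radial search range in pixels.
#' @param n_semi number of semicircular sectors around each pixel.
#' @param n_dirs probing directions per sector.
#' @param step radial sampling step in pixels.
#' @param require_consecutive if `TRUE` (default) the `th3` rule is applied
#'   to the longest circularly-consecutive run of entrance sectors; if
#'   `FALSE`, to their total count.
#' @param comparator_th3 `"at_least"` (default, `run >= th3`) or
#'   `"strict_greater"` (`run > th3`).
#' @param fill if `TRUE`, each positive pixel additionally stamps a filled
#'   disc of radius `r0` into the output mask (off by default: pure
#'   pixel-wise labeling).
#' @return a `detection_config` list.
#' @export
detection_config <- function(th1 = 0.015, th2 = 2L, th3 = 3L,
                             r0 = 4, r1 = 25,
                             n_semi = 8L, n_dirs = 5L, step = 1,
                             require_consecutive = TRUE,
                             comparator_th3 = c("at_least", "strict_greater"),
                             fill = FALSE) {
  comparator_th3 <- match.arg(comparator_th3)
  if (th1 <= 0) stop_config("th1 must be > 0")
  if (th2 < 0 || th2 >= n_dirs) stop_config("need 0 <= th2 < n_dirs")
  if (th3 < 1 || th3 > n_semi) stop_config("need 1 <= th3 <= n_semi")
  if (r0 < 1 || r1 <= r0) stop_config("need r1 > r0 >= 1")
  structure(list(th1 = th1, th2 = as.integer(th2), th3 = as.integer(th3),
                 r0 = r0, r1 = r1, n_semi = as.integer(n_semi),
                 n_dirs = as.integer(n_dirs), step = step,
                 require_consecutive = isTRUE(require_consecutive),
                 comparator_th3 = comparator_th3, fill = isTRUE(fill)),
            class = "detection_config")
}

#' Consecutive intensity differences along a direction
#'
#' `diffs[n] = values[n + 1] - values[n]`: the exact first differences of the
#' radial samples, outward order.
#'
#' @param s a `radial_samples` object from [sample_direction].
#' @return a `diff_series` (numeric vector); empty when fewer than 2 samples
#'   exist (the direction is then trivially constant).
#' @export
radial_differences <- function(s) {
  v <- s$values
  d <- if (length(v) < 2L) numeric(0) else diff(v)
  structure(d, class = "diff_series")
}

#' Non-constant direction test
#'
#' A direction is non-constant when some consecutive-sample difference is a
#' drop larger than `th1`: `df < 0` and `|df| > th1`, both strict.
#'
#' @param d a `diff_series`.
#' @param th1 drop threshold on the normalized intensity scale.
#' @return logical scalar.
#' @export
is_nonconstant <- function(d, th1) {
  any(d < 0 & -d > th1)
}

#' Entrance-area test for one sector
#'
#' Counts the non-constant directions among the sector's `n_dirs` probing
#' directions; the sector is an entrance area to an exudate when the count
#' strictly exceeds `th2`.
#'
#' @param img a normalized [gray_image].
#' @param center integer `c(row, col)`.
#' @param sc a `semicircle_spec`.
#' @param cfg a [detection_config].
#' @return list with `count` (integer) and `entrance` (logical).
#' @export
semicircle_entrance <- function(img, center, sc, cfg = detection_config()) {
  dirs <- make_directions(sc, cfg$n_dirs)
  count <- 0L
  for (d in dirs) {
    s <- sample_direction(img, center, d, cfg$r0, cfg$r1, cfg$step)
    if (is_nonconstant(radial_differences(s), cfg$th1)) count <- count + 1L
  }
  list(count = count, entrance = count > cfg$th2)
}

# Longest circularly-consecutive run of TRUE in a logical vector.
circular_run <- function(flags) {
  n <- length(flags)
  if (all(flags)) return(n)
  if (!any(flags)) return(0L)
  x <- c(flags, flags)
  best <- 0L; cur <- 0L
  for (k in seq_along(x)) {
    cur <- if (x[k]) cur + 1L else 0L
    if (cur > best) best <- cur
  }
  min(best, n)
}

th3_satisfied <- function(value, cfg) {
  if (cfg$comparator_th3 == "at_least") value >= cfg$th3 else value > cfg$th3
}

#' Classify a single pixel
#'
#' The straight-line per-pixel, per-direction, per-radius reading of the
#' method: every sector's directions are sampled with [sample_direction],
#' differenced, and tested; the pixel is exudate when the entrance flags
#' satisfy the `th3` rule. This path is deliberately independent of the
#' vectorized whole-image scan in [detect_exudates] and serves as its
#' reference oracle.
#'
#' @param img a normalized [gray_image].
#' @param center integer `c(row, col)`.
#' @param cfg a [detection_config].
#' @return a `pixel_verdict`: `center`, `nonconstant_counts`,
#'   `entrance_flags`, `is_he`.
#' @export
classify_pixel <- function(img, center, cfg = detection_config()) {
  scs <- make_semicircles(cfg$n_semi)
  counts <- integer(cfg$n_semi)
  for (i in seq_along(scs))
    counts[i] <- semicircle_entrance(img, center, scs[[i]], cfg)$count
  flags <- counts > cfg$th2
  value <- if (cfg$require_consecutive) circular_run(flags) else sum(flags)
  structure(list(center = center, nonconstant_counts = counts,
                 entrance_flags = flags, is_he = th3_satisfied(value, cfg)),
            class = "pixel_verdict")
}

# Per-direction non-constant indicator for every pixel at once: the image is
# shifted by the direction's rounded radial offsets and consecutive shifted
# rasters are differenced. NA (out-of-bounds) pairs never qualify, which
# reproduces the truncation rule exactly because the rounded offsets along a
# ray leave the image monotonically.
.nonconstant_map <- function(m, off, th1) {
  k <- length(off$dy)
  nc <- matrix(FALSE, nrow(m), ncol(m))
  if (k < 2L) return(nc)
  prev <- shift_matrix(m, off$dy[1], off$dx[1])
  for (n in 2:k) {
    cur <- shift_matrix(m, off$dy[n], off$dx[n])
    d <- cur - prev
    nc <- nc | (!is.na(d) & d < 0 & -d > th1)
    prev <- cur
  }
  nc
}

#' Detect hard exudates over a whole image
#'
#' Runs the semicircular radial analysis at every pixel of a normalized
#' intensity image and returns the binary exudate mask. Pixels inside the
#' optional exclusion mask (typically the localized optic disc) are cleared.
#' The scan is fully deterministic; pixels near the border are scanned like
#' any other, with radial samples truncating at the image boundary.
#'
#' @param img a normalized [gray_image] (see [normalize_gray]).
#' @param cfg a [detection_config].
#' @param exclusion optional [binary_mask] of pixels to suppress (same shape).
#' @return a [binary_mask] with meaning `"lesion"`.
#' @export
detect_exudates <- function(img, cfg = detection_config(), exclusion = NULL) {
  stopifnot(inherits(img, "gray_image"))
  m <- img$intensities
  h <- nrow(m); w <- ncol(m)
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "binary_mask"))
    if (!identical(dim(exclusion$labels), dim(m)))
      stop_input("exclusion mask shape does not match image")
  }
  scs <- make_semicircles(cfg$n_semi)
  entrance <- vector("list", cfg$n_semi)
  for (i in seq_along(scs)) {
    count <- matrix(0L, h, w)
    for (d in make_directions(scs[[i]], cfg$n_dirs)) {
      off <- direction_offsets(d$angle, cfg$r0, cfg$r1, cfg$step)
      count <- count + .nonconstant_map(m, off, cfg$th1)
    }
    entrance[[i]] <- count > cfg$th2
  }
  if (cfg$require_consecutive) {
    run <- matrix(0L, h, w)
    best <- matrix(0L, h, w)
    for (k in seq_len(2L * cfg$n_semi)) {
      e <- entrance[[(k - 1L) %% cfg$n_semi + 1L]]
      run <- ifelse(e, run + 1L, 0L)
      best <- pmax(best, run)
    }
    value <- pmin(best, cfg$n_semi)
  } else {
    value <- Reduce(`+`, entrance)
  }
  he <- if (cfg$comparator_th3 == "at_least") value >= cfg$th3
        else value > cfg$th3
  if (cfg$fill) he <- .fill_disc(he, cfg$r0)
  lab <- matrix(as.integer(he), h, w)
  if (!is.null(exclusion)) lab[exclusion$labels == 1L] <- 0L
  binary_mask(lab, meaning = "lesion")
}

# Morphological dilation of a logical matrix by a filled disc of radius r.
.fill_disc <- function(he, r) {
  out <- he
  r <- ceiling(r)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy * dy + dx * dx <= r * r && !(dy == 0 && dx == 0)) {
      s <- shift_matrix(he * 1.0, dy, dx)
      out <- out | (!is.na(s) & s > 0)
    }
  }
  out
}

#' Reference whole-image detection (naive loop)
#'
#' A straight-line per-pixel, per-direction, per-radius transcription of the
#' method: for every pixel and every direction the polar sample coordinates
#' are computed from sine/cosine on the spot, differenced, and tested with
#' the drop condition; sector counts and the consecutive-sector rule are
#' evaluated with explicit loops. Independent of the shifted-raster algebra
#' in [detect_exudates] and used as its oracle on small images. Slow by
#' design.
#'
#' @inheritParams detect_exudates
#' @return a [binary_mask].
#' @export
detect_exudates_reference <- function(img, cfg = detection_config(),
                                      exclusion = NULL) {
  stopifnot(inherits(img, "gray_image"))
  m <- img$intensities
  h <- nrow(m); w <- ncol(m)
  radii <- seq(cfg$r0, cfg$r1, by = cfg$step)
  # Per-direction rounded offsets, derived here from scratch (trig + half-up
  # rounding + duplicate collapse). Center-independent, so computed once;
  # everything per pixel below is explicit gather-and-test loops.
  angles <- unlist(lapply(make_semicircles(cfg$n_semi), function(sc)
    vapply(make_directions(sc, cfg$n_dirs), `[[`, numeric(1), "angle")))
  sector_of <- rep(seq_len(cfg$n_semi), each = cfg$n_dirs)
  offs <- lapply(angles, function(a) {
    dro <- floor(-radii * sin(a) + 0.5)   # row offset, +y up
    dco <- floor(radii * cos(a) + 0.5)
    keep <- c(TRUE, dro[-1] != dro[-length(dro)] | dco[-1] != dco[-length(dco)])
    list(dr = as.integer(dro[keep]), dc = as.integer(dco[keep]))
  })
  nd <- length(angles)
  lab <- matrix(0L, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    counts <- integer(cfg$n_semi)
    for (d in seq_len(nd)) {
      o <- offs[[d]]
      rows <- r + o$dr
      cols <- cc + o$dc
      oob <- rows < 1L | rows > h | cols < 1L | cols > w
      n <- if (any(oob)) which.max(oob) - 1L else length(rows)
      if (n < 2L) next
      v <- m[cols[seq_len(n)] * h - h + rows[seq_len(n)]]  # [row, col] gather
      df <- v[-1] - v[-n]
      if (any(df < 0 & -df > cfg$th1)) {
        s <- sector_of[d]
        counts[s] <- counts[s] + 1L
      }
    }
    flags <- counts > cfg$th2
    value <- if (cfg$require_consecutive) circular_run(flags) else sum(flags)
    lab[r, cc] <- as.integer(th3_satisfied(value, cfg))
  }
  if (cfg$fill) lab <- matrix(as.integer(.fill_disc(lab == 1L, cfg$r0)), h, w)
  if (!is.null(exclusion)) lab[exclusion$labels == 1L] <- 0L
  binary_mask(lab, meaning = "lesion")
}
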