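# Semicircular sectors, their directions, and radial pixel sampling.
#
# Axis convention (stated once, obeyed everywhere): pixel (row, col) with
# 1-based indices; angle 0 points along +x (increasing column), angles grow
# counter-clockwise with +y pointing up, i.e. row index decreasing.
# Polar-to-grid rounding is half-away-from-zero (see rhu()), which makes the
# rounded offsets independent of the (integer) center pixel.

#' Build the semicircular sector partition
#'
#' Partitions the full circle around a pixel into `n_semi` equal angular
#' sectors. With the default `n_semi = 8` sector `i` covers
#' `[(i-1) * pi/4, i * pi/4]`.
#'
#' @param n_semi number of sectors (>= 2).
#' @return a list of `semicircle_spec` objects with fields `index`,
#'   `angle_lo`, `angle_hi`.
#' @export
make_semicircles <- function(n_semi = 8L) {
  if (!is.numeric(n_semi) || n_semi < 2)
    stop_config("n_semi must be >= 2")
  n_semi <- as.integer(n_semi)
  w <- 2 * pi / n_semi
  lapply(seq_len(n_semi), function(i) {
    structure(list(index = i, angle_lo = (i - 1) * w, angle_hi = i * w),
              class = "semicircle_spec")
  })
}

#' Place the probing directions inside one sector
#'
#' The sector's angular interval is divided into `n_dirs` equal sub-intervals
#' and one direction is placed at the midpoint of each, so no direction ever
#' lies on a sector boundary and adjacent sectors share no direction.
#'
#' @param sc a `semicircle_spec` from [make_semicircles].
#' @param n_dirs directions per sector (>= 1).
#' @return a list of `direction_spec` objects with fields `semicircle`,
#'   `index`, `angle`.
#' @export
make_directions <- function(sc, n_dirs = 5L) {
  stopifnot(inherits(sc, "semicircle_spec"))
  if (!is.numeric(n_dirs) || n_dirs < 1)
    stop_config("n_dirs must be >= 1")
  n_dirs <- as.integer(n_dirs)
  span <- sc$angle_hi - sc$angle_lo
  lapply(seq_len(n_dirs), function(j) {
    structure(list(semicircle = sc$index, index = j,
                   angle = sc$angle_lo + (j - 0.5) * span / n_dirs),
              class = "direction_spec")
  })
}

# Rounded grid offsets (dy = row shift, dx = col shift) for one direction,
# radii r0, r0+step, ..., <= r1, with consecutive duplicate cells collapsed
# (keeping the first). Independent of the center pixel because rounding is
# half-away-from-zero and centers are integer.
direction_offsets <- function(angle, r0, r1, step = 1) {
  radii <- seq(r0, r1, by = step)
  dx <- rhu(radii * cos(angle))
  dy <- rhu(-radii * sin(angle))  # +y up means row decreases
  keep <- c(TRUE, dx[-1] != dx[-length(dx)] | dy[-1] != dy[-length(dy)])
  list(radii = radii[keep], dy = as.integer(dy[keep]), dx = as.integer(dx[keep]))
}

#' Sample image intensities along one direction
#'
#' Walks outward from `center` along direction `d` at radii
#' `r0, r0 + step, ...  <= r1`, rounding each polar position to the pixel
#' grid. Consecutive samples that round to the same pixel are collapsed
#' (keeping the first); the sample list is truncated at the first position
#' that falls outside the image.
#'
#' @param img a [gray_image].
#' @param center integer `c(row, col)`, 1-based, inside the image.
#' @param d a `direction_spec` (or any list with an `angle` field).
#' @param r0,r1 inner and outer search radii in pixels (`r1 > r0 >= 1`).
#' @param step radial step in pixels.
#' @return a `radial_samples` object: fields `direction`, `radii`, `coords`
#'   (n x 2 matrix of row, col) and `values`.
#' @export
sample_direction <- function(img, center, d, r0 = 4, r1 = 25, step = 1) {
  stopifnot(inherits(img, "gray_image"))
  if (r0 < 1 || r1 <= r0 || step <= 0)
    stop_config("need r0 >= 1, r1 > r0, step > 0")
  h <- nrow(img$intensities); w <- ncol(img$intensities)
  if (center[1] < 1 || center[1] > h || center[2] < 1 || center[2] > w)
    stop_input("center (", center[1], ", ", center[2], ") outside image ",
               h, " x ", w)
  off <- direction_offsets(d$angle, r0, r1, step)
  rows <- center[1] + off$dy
  cols <- center[2] + off$dx
  inb <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  n <- if (all(inb)) length(inb) else which(!inb)[1] - 1L
  idx <- seq_len(n)
  structure(list(direction = d,
                 radii = off$radii[idx],
                 coords = cbind(row = rows[idx], col = cols[idx]),
                 values = img$intensities[cbind(rows[idx], cols[idx])]),
            class = "radial_samples")
}
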