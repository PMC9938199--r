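#' Optic-disc localizer parameters
#'
#' The optic disc is the brightest circular structure in a fundus image and
#' the main source of false-positive bright-lesion detections; it is located
#' by looking for a circle of known (manually measured) radius in the edge
#' map and picking, among the candidate circles, the one with the brightest
#' ray. The expected radius is a per-dataset input; when `od_radius` is
#' `NULL` it defaults to `round(0.08 * image width)` at use time.
#'
#' @param od_radius expected disc radius in pixels (>= 3), or `NULL` for the
#'   image-width default.
#' @param median_kernel odd side length of the median pre-filter (>= 3).
#' @param edge_threshold gradient-magnitude cutoff in `[0, 1]` (Sobel
#'   magnitude normalized by its maximum attainable response).
#' @param n_sectors_per_quarter rays cast per circle quarter.
#' @param radius_tolerance band half-width (pixels) around `od_radius` within
#'   which an edge pixel counts as a ray hit.
#' @param quarter_dir_threshold minimum fraction of a quarter's rays that
#'   must hit for the quarter to be a candidate.
#' @param dilation pixels added to `od_radius` when building the exclusion
#'   mask.
#' @param stride center-search grid stride in pixels (refined to stride 1 in
#'   a 5x5 neighborhood of the best cell).
#' @return an `od_config` list.
#' @export
od_config <- function(od_radius = NULL, median_kernel = 5L,
                      edge_threshold = 0.1, n_sectors_per_quarter = 8L,
                      radius_tolerance = 2, quarter_dir_threshold = 0.5,
                      dilation = 2, stride = 2L) {
  if (!is.null(od_radius) && od_radius < 3) stop_config("od_radius must be >= 3")
  if (median_kernel < 3 || median_kernel %% 2 == 0)
    stop_config("median_kernel must be odd and >= 3")
  if (quarter_dir_threshold <= 0 || quarter_dir_threshold > 1)
    stop_config("quarter_dir_threshold must be in (0, 1]")
  structure(list(od_radius = od_radius,
                 median_kernel = as.integer(median_kernel),
                 edge_threshold = edge_threshold,
                 n_sectors_per_quarter = as.integer(n_sectors_per_quarter),
                 radius_tolerance = radius_tolerance,
                 quarter_dir_threshold = quarter_dir_threshold,
                 dilation = dilation, stride = as.integer(stride)),
            class = "od_config")
}

resolve_od_radius <- function(cfg, width) {
  cfg$od_radius %||% max(3L, round(0.08 * width))
}

# Matrix shift with replicated (clamped) borders; used by the smoothing and
# gradient filters so border pixels see their nearest neighbors.
shift_rep <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[clamp(seq_len(h) + dy, 1L, h), clamp(seq_len(w) + dx, 1L, w), drop = FALSE]
}

median_filter <- function(m, k) {
  r <- (k - 1L) %/% 2L
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  z <- vapply(seq_len(nrow(offs)),
              function(i) as.vector(shift_rep(m, offs$dy[i], offs$dx[i])),
              numeric(length(m)))
  matrix(apply(z, 1L, stats::median.default), nrow(m), ncol(m))
}

sobel_edges <- function(m, threshold) {
  gx <- 2 * (shift_rep(m, 0L, 1L) - shift_rep(m, 0L, -1L)) +
        (shift_rep(m, -1L, 1L) - shift_rep(m, -1L, -1L)) +
        (shift_rep(m, 1L, 1L) - shift_rep(m, 1L, -1L))
  gy <- 2 * (shift_rep(m, 1L, 0L) - shift_rep(m, -1L, 0L)) +
        (shift_rep(m, 1L, -1L) - shift_rep(m, -1L, -1L)) +
        (shift_rep(m, 1L, 1L) - shift_rep(m, -1L, 1L))
  mag <- sqrt(gx^2 + gy^2) / (4 * sqrt(2))  # max response of each kernel is 4
  matrix(as.integer(mag > threshold), nrow(m), ncol(m))
}

#' Smooth and edge-detect for optic-disc search
#'
#' Median-filters the intensity image (noise suppression that preserves the
#' disc rim) and extracts a binary boundary map by thresholding the Sobel
#' gradient magnitude.
#'
#' @param img a [gray_image].
#' @param cfg an [od_config].
#' @return list with `smoothed` ([gray_image]) and `edges` ([binary_mask],
#'   meaning `"optic_disc"`).
#' @export
preprocess_for_od <- function(img, cfg = od_config()) {
  stopifnot(inherits(img, "gray_image"))
  sm <- median_filter(img$intensities, cfg$median_kernel)
  list(smoothed = gray_image(sm, channel_tag = img$channel_tag),
       edges = binary_mask(sobel_edges(sm, cfg$edge_threshold),
                           meaning = "optic_disc"))
}

# Rounded offsets of the ray angles (4 quarters x n sectors, midpoint rule)
# sampled over the given radii, deduplicated per ray.
.ray_offsets <- function(n_per_quarter, radii) {
  angles <- unlist(lapply(0:3, function(q) {
    lo <- q * pi / 2
    lo + (seq_len(n_per_quarter) - 0.5) * (pi / 2) / n_per_quarter
  }))
  lapply(angles, function(a) {
    dx <- rhu(radii * cos(a)); dy <- rhu(-radii * sin(a))
    keep <- !duplicated(cbind(dy, dx))
    list(dy = as.integer(dy[keep]), dx = as.integer(dx[keep]), angle = a)
  })
}

.band_radii <- function(od_radius, tol) {
  seq(max(1, od_radius - tol), od_radius + tol, by = 0.5)
}

#' Circle-candidacy test at one center
#'
#' The circle of radius `od_radius` around `center` is divided into four
#' quarters; each quarter casts `n_sectors_per_quarter` rays, and a ray hits
#' when an edge pixel lies on it within `od_radius +/- radius_tolerance`. A
#' quarter is ok when at least `quarter_dir_threshold` of its rays hit; the
#' center is a candidate when all four quarters are ok.
#'
#' @param edges binary edge map from [preprocess_for_od].
#' @param center integer `c(row, col)`.
#' @param cfg an [od_config].
#' @return list with `quarters_ok` (4 logicals) and `candidate` (logical).
#' @export
quarter_candidacy <- function(edges, center, cfg = od_config()) {
  stopifnot(inherits(edges, "binary_mask"))
  e <- edges$labels
  h <- nrow(e); w <- ncol(e)
  if (center[1] < 1 || center[1] > h || center[2] < 1 || center[2] > w)
    stop_input("center outside image")
  rad <- resolve_od_radius(cfg, w)
  rays <- .ray_offsets(cfg$n_sectors_per_quarter,
                       .band_radii(rad, cfg$radius_tolerance))
  hit <- vapply(rays, function(o) {
    rr <- center[1] + o$dy; cc <- center[2] + o$dx
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    any(e[cbind(rr[ok], cc[ok])] == 1L)
  }, logical(1))
  npq <- cfg$n_sectors_per_quarter
  quarters_ok <- vapply(0:3, function(q)
    mean(hit[q * npq + seq_len(npq)]) >= cfg$quarter_dir_threshold, logical(1))
  list(quarters_ok = quarters_ok, candidate = all(quarters_ok))
}

# Candidacy for every pixel at once via shifted edge maps; returns the
# all-quarters-ok map and the total ray-hit count map (ring-fit strength).
.candidate_map <- function(e, cfg, rad) {
  rays <- .ray_offsets(cfg$n_sectors_per_quarter,
                       .band_radii(rad, cfg$radius_tolerance))
  npq <- cfg$n_sectors_per_quarter
  ok_all <- matrix(TRUE, nrow(e), ncol(e))
  hits <- matrix(0L, nrow(e), ncol(e))
  for (q in 0:3) {
    cnt <- matrix(0L, nrow(e), ncol(e))
    for (o in rays[q * npq + seq_len(npq)]) {
      hit <- matrix(FALSE, nrow(e), ncol(e))
      for (i in seq_along(o$dy)) {
        s <- shift_matrix(e * 1.0, o$dy[i], o$dx[i])
        hit <- hit | (!is.na(s) & s == 1)
      }
      cnt <- cnt + hit
    }
    hits <- hits + cnt
    ok_all <- ok_all & (cnt / npq >= cfg$quarter_dir_threshold)
  }
  list(ok = ok_all, hits = hits)
}

# Group candidate grid cells into 8-connected components (allowing for the
# stride spacing); each component is one candidate circle.
.cluster_candidates <- function(idx, stride) {
  n <- nrow(idx)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      nb <- which(comp == 0L &
                  abs(idx[, 1] - idx[k, 1]) <= stride &
                  abs(idx[, 2] - idx[k, 2]) <= stride)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Mean intensity along each ray over radii [0, od_radius]; returns the max.
.brightest_ray_mean <- function(sm, center, cfg, rad) {
  rays <- .ray_offsets(cfg$n_sectors_per_quarter, 0:rad)  # same angles as candidacy
  h <- nrow(sm); w <- ncol(sm)
  best <- -Inf
  for (o in rays) {
    rr <- center[1] + o$dy; cc <- center[2] + o$dx
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    if (!any(ok)) next
    v <- mean(sm[cbind(rr[ok], cc[ok])])
    if (v > best) best <- v
  }
  best
}

#' Locate the optic disc
#'
#' Scans candidate centers on a `stride`-spaced grid with
#' [quarter_candidacy]; contiguous passing cells are one candidate circle,
#' whose center is estimated as the ray-hit-count weighted centroid of its
#' cells (rounded). Among the candidate circles, the one whose brightest
#' ray (maximum mean intensity over radii `[0, od_radius]` on the smoothed
#' image) is highest wins; ties break deterministically to the smaller row,
#' then smaller column.
#'
#' @param img the smoothed [gray_image] (from [preprocess_for_od]).
#' @param edges the binary edge map (from [preprocess_for_od]).
#' @param cfg an [od_config].
#' @return an `od_result` (fields `center`, `radius`,
#'   `brightest_direction_mean`, `candidate_count`) or `NULL` when no
#'   candidate circle exists.
#' @export
select_optic_disc <- function(img, edges, cfg = od_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(edges, "binary_mask"))
  sm <- img$intensities
  e <- edges$labels
  rad <- resolve_od_radius(cfg, ncol(sm))
  cand <- .candidate_map(e, cfg, rad)
  grid <- matrix(FALSE, nrow(sm), ncol(sm))
  grid[seq(1L, nrow(sm), by = cfg$stride), seq(1L, ncol(sm), by = cfg$stride)] <- TRUE
  idx <- which(cand$ok & grid, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  comp <- .cluster_candidates(idx, cfg$stride)
  best <- NULL; best_v <- -Inf
  for (ci in sort(unique(comp))) {
    cells <- idx[comp == ci, , drop = FALSE]
    wt <- as.numeric(cand$hits[cells])
    if (sum(wt) <= 0) wt <- rep(1, nrow(cells))
    ctr <- c(rhu(sum(cells[, 1] * wt) / sum(wt)),
             rhu(sum(cells[, 2] * wt) / sum(wt)))
    ctr <- as.integer(clamp(ctr, 1L, c(nrow(sm), ncol(sm))))
    v <- .brightest_ray_mean(sm, ctr, cfg, rad)
    if (v > best_v + 1e-15 ||
        (!is.null(best) && abs(v - best_v) <= 1e-15 &&
         (ctr[1] < best[1] || (ctr[1] == best[1] && ctr[2] < best[2])))) {
      best <- ctr; best_v <- v
    }
  }
  structure(list(center = best, radius = rad,
                 brightest_direction_mean = best_v,
                 candidate_count = nrow(idx)),
            class = "od_result")
}

#' Optic-disc exclusion mask
#'
#' A filled disc of radius `od_radius + dilation` at the localized center,
#' clipped to the image; used to suppress bright-lesion false positives on
#' the disc.
#'
#' @param result an `od_result` from [select_optic_disc].
#' @param shape integer `c(H, W)`.
#' @param cfg an [od_config].
#' @return a [binary_mask] with meaning `"optic_disc"`.
#' @export
od_exclusion_mask <- function(result, shape, cfg = od_config()) {
  if (is.null(result)) stop_input("od_exclusion_mask: no optic-disc result")
  r2 <- (result$radius + cfg$dilation)^2
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  inside <- (rows - result$center[1])^2 + (cols - result$center[2])^2 <= r2
  binary_mask(matrix(as.integer(inside), shape[1], shape[2]),
              meaning = "optic_disc")
}

#' One-call optic-disc localization
#'
#' Convenience wrapper: preprocess, select, and return both the result and
#' the exclusion mask.
#'
#' @param img a [gray_image] (normalized working channel).
#' @param cfg an [od_config].
#' @return list with `result` (`od_result` or `NULL`) and `mask`
#'   ([binary_mask] or `NULL`).
#' @export
locate_optic_disc <- function(img, cfg = od_config()) {
  pp <- preprocess_for_od(img, cfg)
  res <- select_optic_disc(pp$smoothed, pp$edges, cfg)
  list(result = res,
       mask = if (is.null(res)) NULL
              else od_exclusion_mask(res, dim(img$intensities), cfg))
}
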