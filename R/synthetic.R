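# Seeded generator of fundus-like scenes with exact ground truth.
#
# What it emulates: a smooth bright-ish background with low-frequency
# illumination drift, dark curvilinear vessels, bright sharp-margin lesions
# of varied star-convex shape, and one bright circular optic disc. What it
# does not emulate: photoreceptor texture, hemorrhages/micro-aneurysms,
# camera vignetting masks, or realistic color rendition.

#' Synthetic scene parameters
#'
#' Defaults describe a desk-scale fundus-like phantom: 256 x 256, six
#' lesions with radii 5-20 px and green-channel contrast 0.10-0.30 above
#' background, three vessels 0.2 darker than background, one optic disc of
#' radius 20 px and contrast 0.3, and Gaussian pixel noise of sd 0.01.
#'
#' @param seed integer RNG seed; each component (background, vessels,
#'   lesions, noise) uses a sub-seed derived from it, so toggling one
#'   component does not shift the others.
#' @param size integer `c(H, W)`.
#' @param background list with `base` level and low-frequency `amplitude`
#'   (normalized units).
#' @param n_lesions number of lesions.
#' @param lesion_radius_range `c(min, max)` lesion radius in pixels (>= 2).
#' @param lesion_contrast_range `c(min, max)` contrast above background.
#' @param lesion_shape `"star_convex"`, `"disc"`, or `"ellipse"`.
#' @param n_vessels number of vessels.
#' @param vessel_darkness depression of the vessel core below background.
#' @param od_center `"auto"` or integer `c(row, col)`.
#' @param od_radius optic-disc radius in pixels.
#' @param od_contrast optic-disc brightness above background.
#' @param noise_sigma sd of additive Gaussian noise (clipped to `[0, 1]`).
#' @param feather lesion edge ramp width in pixels (0 = hard margin).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(seed = 1L, size = c(256L, 256L),
                       background = list(base = 0.45, amplitude = 0.08),
                       n_lesions = 6L,
                       lesion_radius_range = c(5, 20),
                       lesion_contrast_range = c(0.1, 0.3),
                       lesion_shape = c("star_convex", "disc", "ellipse"),
                       n_vessels = 3L, vessel_darkness = 0.2,
                       od_center = "auto", od_radius = 20,
                       od_contrast = 0.3,
                       noise_sigma = 0.01, feather = 0) {
  lesion_shape <- match.arg(lesion_shape)
  if (lesion_contrast_range[1] <= 0) stop_config("lesion contrast must be > 0")
  if (lesion_radius_range[1] < 2) stop_config("lesion radii must be >= 2")
  if (2 * (lesion_radius_range[2] + 2) >= min(size))
    stop_config("lesions do not fit in the image")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 background = background, n_lesions = as.integer(n_lesions),
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast_range = lesion_contrast_range,
                 lesion_shape = lesion_shape, n_vessels = as.integer(n_vessels),
                 vessel_darkness = vessel_darkness, od_center = od_center,
                 od_radius = od_radius, od_contrast = od_contrast,
                 noise_sigma = noise_sigma, feather = feather),
            class = "scene_spec")
}

.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299709) %% 2147483629)
}

.coord_grids <- function(h, w) {
  list(rows = matrix(seq_len(h), h, w),
       cols = matrix(seq_len(w), h, w, byrow = TRUE))
}

.gen_background <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  set.seed(.sub_seed(spec$seed, 1L))
  g <- .coord_grids(h, w)
  f <- matrix(0, h, w)
  for (m in 1:3) {
    u <- runif(1, -1.5, 1.5); v <- runif(1, -1.5, 1.5)
    b <- runif(1, 0.3, 1); psi <- runif(1, 0, 2 * pi)
    f <- f + b * cos(2 * pi * (u * g$rows / h + v * g$cols / w) + psi)
  }
  mx <- max(abs(f))
  if (mx > 0) f <- f / mx
  spec$background$base + spec$background$amplitude * f
}

.gen_vessel_depth <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  set.seed(.sub_seed(spec$seed, 2L))
  depth <- matrix(0, h, w)
  for (v in seq_len(spec$n_vessels)) {
    side <- sample.int(4L, 1L)
    pos <- switch(side,
      c(1, runif(1, 1, w)), c(h, runif(1, 1, w)),
      c(runif(1, 1, h), 1), c(runif(1, 1, h), w))
    heading <- switch(side, pi / 2, -pi / 2, 0, pi) + runif(1, -0.6, 0.6)
    # heading in image terms: dx = cos, dy = +sin moves down rows here
    width <- runif(1, 2, 4)
    sigma <- width / 2
    rad <- ceiling(2.5 * sigma)
    for (s in seq_len(2L * max(h, w))) {
      r0 <- pos[1]; c0 <- pos[2]
      if (r0 < -5 || r0 > h + 5 || c0 < -5 || c0 > w + 5) break
      rr <- clamp(round(r0) + (-rad:rad), 1L, h)
      cc <- clamp(round(c0) + (-rad:rad), 1L, w)
      rr <- unique(rr); cc <- unique(cc)
      d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
      depth[rr, cc] <- pmax(depth[rr, cc],
                            spec$vessel_darkness * exp(-d2 / (2 * sigma^2)))
      heading <- heading + rnorm(1, 0, 0.12)
      pos <- pos + 2 * c(sin(heading), cos(heading))
    }
  }
  depth
}

.place_od <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  if (!identical(spec$od_center, "auto")) return(as.integer(spec$od_center))
  set.seed(.sub_seed(spec$seed, 3L))
  margin <- spec$od_radius + 8
  row <- round(runif(1, margin, h - margin))
  col <- if (runif(1) < 0.5) round(runif(1, margin, margin + w / 5))
         else round(runif(1, w - margin - w / 5, w - margin))
  c(as.integer(row), as.integer(col))
}

.star_radius_fun <- function(mean_radius, amps, phases) {
  force(mean_radius); force(amps); force(phases)
  function(theta) {
    s <- rep(1, length(theta))
    for (k in seq_along(amps)) s <- s + amps[k] * cos(k * theta + phases[k])
    mean_radius * s
  }
}

.draw_lesion_shape <- function(spec) {
  rmin <- spec$lesion_radius_range[1]; rmax <- spec$lesion_radius_range[2]
  shape <- spec$lesion_shape
  if (shape == "disc") {
    m <- runif(1, rmin, rmax)
    list(shape = "disc", mean_radius = m, amps = numeric(0),
         phases = numeric(0), max_radius = m)
  } else if (shape == "ellipse") {
    # two-fold harmonic gives an oval star-convex boundary within range
    a <- runif(1, 0.05, 0.25)
    m <- runif(1, rmin / (1 - a), rmax / (1 + a))
    list(shape = "ellipse", mean_radius = m, amps = c(0, a),
         phases = c(0, runif(1, 0, 2 * pi)), max_radius = m * (1 + a))
  } else {
    raw <- runif(4)
    total <- runif(1, 0.1, 0.3)
    amps <- total * raw / sum(raw) * sample(c(-1, 1), 4, replace = TRUE)
    a <- sum(abs(amps))
    m <- runif(1, rmin / (1 - a), rmax / (1 + a))
    list(shape = "star_convex", mean_radius = m, amps = amps,
         phases = runif(4, 0, 2 * pi), max_radius = m * (1 + a))
  }
}

.gen_lesions <- function(spec, field, od_center) {
  h <- spec$size[1]; w <- spec$size[2]
  set.seed(.sub_seed(spec$seed, 4L))
  he <- matrix(0L, h, w)
  records <- list()
  placed <- matrix(numeric(0), ncol = 3)  # row, col, max_radius
  for (i in seq_len(spec$n_lesions)) {
    sh <- .draw_lesion_shape(spec)
    ok <- FALSE
    for (try in seq_len(300L)) {
      ctr <- c(round(runif(1, sh$max_radius + 3, h - sh$max_radius - 2)),
               round(runif(1, sh$max_radius + 3, w - sh$max_radius - 2)))
      if (sqrt(sum((ctr - od_center)^2)) <=
          spec$od_radius + sh$max_radius + 6) next
      if (nrow(placed) > 0 &&
          any(sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2) <=
              placed[, 3] + sh$max_radius + 3)) next
      ok <- TRUE; break
    }
    if (!ok) stop_config("could not place lesion ", i,
                         ": geometry does not fit the image")
    contrast <- runif(1, spec$lesion_contrast_range[1],
                      spec$lesion_contrast_range[2])
    rho <- .star_radius_fun(sh$mean_radius, sh$amps, sh$phases)
    b <- ceiling(sh$max_radius) + ceiling(spec$feather) + 1L
    rr <- max(1L, ctr[1] - b):min(h, ctr[1] + b)
    cc <- max(1L, ctr[2] - b):min(w, ctr[2] + b)
    dy <- matrix(rr - ctr[1], length(rr), length(cc))
    dx <- matrix(cc - ctr[2], length(rr), length(cc), byrow = TRUE)
    theta <- atan2(-dy, dx)        # +y up
    dist <- sqrt(dy^2 + dx^2)
    bound <- rho(theta)
    inside <- dist <= bound
    # flat plateau: brightest local background + contrast, so every margin
    # crossing drops by at least the lesion's contrast
    level <- max(field[rr, cc][inside]) + contrast
    patch <- field[rr, cc]
    patch[inside] <- level
    if (spec$feather > 0) {
      t <- dist - bound
      ramp <- !inside & t < spec$feather
      patch[ramp] <- pmax(patch[ramp],
                          field[rr, cc][ramp] +
                            contrast * (1 - t[ramp] / spec$feather))
    }
    field[rr, cc] <- patch
    hm <- he[rr, cc]; hm[inside] <- 1L; he[rr, cc] <- hm
    placed <- rbind(placed, c(ctr, sh$max_radius))
    records[[i]] <- list(center = ctr, shape = sh$shape,
                         mean_radius = sh$mean_radius, amps = sh$amps,
                         phases = sh$phases, contrast = contrast,
                         plateau = level)
  }
  list(field = field, he = he, records = records)
}

#' Generate a synthetic fundus-like scene
#'
#' Deterministic given `spec$seed`. Lesions are painted as flat plateaus at
#' (local background maximum + contrast) with hard margins, so every
#' boundary crossing has a single-step drop of at least the lesion's
#' contrast before noise; lesion and optic-disc masks are recorded exactly
#' and are disjoint by construction. When `noise_sigma == 0` and
#' `feather == 0` the generator self-verifies the margin contract by ray
#' tracing (see [check_lesion_margins]) and warns on violation.
#'
#' @param spec a [scene_spec].
#' @return a `synthetic_scene`: fields `image` ([rgb_image], lesions live in
#'   the green channel), `he_mask`, `od_mask` ([binary_mask]), `od_center`,
#'   `od_radius`, `lesion_records`, `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  field <- .gen_background(spec)
  field <- field - .gen_vessel_depth(spec)
  od_center <- .place_od(spec)
  g <- .coord_grids(h, w)
  od_dist <- sqrt((g$rows - od_center[1])^2 + (g$cols - od_center[2])^2)
  ramp <- clamp((spec$od_radius + 1 - od_dist) / 2, 0, 1)  # 2 px soft rim
  field <- field + spec$od_contrast * ramp
  od_mask <- matrix(as.integer(od_dist <= spec$od_radius), h, w)
  les <- .gen_lesions(spec, field, od_center)
  green <- clamp(les$field, 0, 1)
  red <- clamp(0.55 + 0.4 * green, 0, 1)
  blue <- clamp(0.25 * green, 0, 1)
  if (spec$noise_sigma > 0) {
    set.seed(.sub_seed(spec$seed, 5L))
    green <- clamp(green + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w), 0, 1)
    red <- clamp(red + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w), 0, 1)
    blue <- clamp(blue + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w), 0, 1)
  }
  img <- rgb_image(array(c(rhu(red * 255), rhu(green * 255), rhu(blue * 255)),
                         dim = c(h, w, 3)), path = "<synthetic>")
  scene <- structure(list(image = img,
                          he_mask = binary_mask(les$he, "lesion"),
                          od_mask = binary_mask(od_mask, "optic_disc"),
                          od_center = od_center, od_radius = spec$od_radius,
                          lesion_records = les$records, spec = spec),
                     class = "synthetic_scene")
  if (spec$noise_sigma == 0 && spec$feather == 0 && spec$n_lesions > 0) {
    chk <- check_lesion_margins(scene)
    if (chk$min_margin_drop <= 0.015)
      warning("lesion margin contract violated: min drop ",
              format(chk$min_margin_drop))
  }
  scene
}

#' Verify the lesion margin contract of a scene
#'
#' For every lesion, traces rays outward from its center on the normalized
#' green channel and measures the largest single-step intensity drop near
#' each boundary crossing. A healthy noise-free scene has every such drop
#' above the detection threshold `th1` (and in practice close to the
#' lesion's contrast).
#'
#' @param scene a `synthetic_scene`.
#' @param n_rays rays per lesion.
#' @return list with `min_margin_drop` and `per_lesion` vector.
#' @export
check_lesion_margins <- function(scene, n_rays = 16L) {
  img <- normalize_gray(extract_channel(scene$image, "green"))
  m <- img$intensities
  h <- nrow(m); w <- ncol(m)
  per <- vapply(scene$lesion_records, function(rec) {
    rho <- .star_radius_fun(rec$mean_radius, rec$amps, rec$phases)
    worst <- Inf
    for (a in (seq_len(n_rays) - 0.5) * 2 * pi / n_rays) {
      bound <- rho(a)
      radii <- seq(0, bound + 3, by = 1)
      rr <- rec$center[1] + rhu(-radii * sin(a))
      cc <- rec$center[2] + rhu(radii * cos(a))
      keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      # drop duplicated grid cells like the detector's sampler does
      dup <- c(FALSE, rr[-1] == rr[-length(rr)] & cc[-1] == cc[-length(cc)])
      keep <- keep & !dup
      v <- m[cbind(rr[keep], cc[keep])]
      radk <- radii[keep]
      if (length(v) < 2) next
      drops <- v[-length(v)] - v[-1]
      # only steps near the boundary crossing count as the margin
      near <- radk[-1] >= bound - 2 & radk[-length(radk)] <= bound + 2
      if (!any(near)) next
      worst <- min(worst, max(drops[near]))
    }
    worst
  }, numeric(1))
  list(min_margin_drop = min(per), per_lesion = per)
}

#' Write a scene to disk
#'
#' Writes `image.png`, `he_mask.png`, `od_mask.png` and a `scene.json`
#' sidecar holding the generating spec and the lesion records, so the scene
#' can be reloaded (or regenerated from its seed) bit-exactly.
#'
#' @param scene a `synthetic_scene`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
scene_to_disk <- function(scene, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_input("cannot create directory ", dir)
  write_rgb(scene$image, file.path(dir, "image.png"))
  write_mask(scene$he_mask, file.path(dir, "he_mask.png"))
  write_mask(scene$od_mask, file.path(dir, "od_mask.png"))
  side <- list(spec = unclass(scene$spec),
               od_center = scene$od_center, od_radius = scene$od_radius,
               lesion_records = scene$lesion_records)
  jsonlite::write_json(side, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Reload a scene written by [scene_to_disk]
#'
#' @param dir directory holding `image.png`, the mask PNGs and `scene.json`.
#' @return a `synthetic_scene`.
#' @export
load_scene <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  sp <- side$spec
  spec <- scene_spec(seed = sp$seed, size = sp$size,
                     background = as.list(sp$background),
                     n_lesions = sp$n_lesions,
                     lesion_radius_range = sp$lesion_radius_range,
                     lesion_contrast_range = sp$lesion_contrast_range,
                     lesion_shape = sp$lesion_shape,
                     n_vessels = sp$n_vessels,
                     vessel_darkness = sp$vessel_darkness,
                     od_center = if (identical(sp$od_center, "auto")) "auto"
                                 else as.integer(sp$od_center),
                     od_radius = sp$od_radius, od_contrast = sp$od_contrast,
                     noise_sigma = sp$noise_sigma, feather = sp$feather)
  recs <- side$lesion_records
  if (is.data.frame(recs)) recs <- lapply(seq_len(nrow(recs)), function(i) {
    r <- lapply(recs, function(col) if (is.list(col)) col[[i]] else col[i])
    r$center <- as.integer(unlist(r$center))
    r$amps <- as.numeric(unlist(r$amps)); r$phases <- as.numeric(unlist(r$phases))
    r
  })
  structure(list(image = load_rgb(file.path(dir, "image.png")),
                 he_mask = read_mask(file.path(dir, "he_mask.png"), "lesion"),
                 od_mask = read_mask(file.path(dir, "od_mask.png"), "optic_disc"),
                 od_center = as.integer(side$od_center),
                 od_radius = side$od_radius,
                 lesion_records = recs, spec = spec),
            class = "synthetic_scene")
}
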