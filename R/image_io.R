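#' Color fundus image container
#'
#' A thin S3 wrapper around an `H x W x 3` integer array of 8-bit samples
#' (0-255, channel order red, green, blue), tagged with its source path.
#'
#' @param pixels numeric or integer array `H x W x 3`, values in 0-255.
#' @param path optional source identifier.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_input("rgb_image: pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_input("rgb_image: empty raster")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, path = path), class = "rgb_image")
}

#' Single-channel intensity image
#'
#' The working representation of the detector: a real-valued `H x W` raster
#' with intensities in `[0, 1]`, tagged with the channel it was derived from.
#'
#' @param intensities numeric matrix with values in `[0, 1]`.
#' @param channel_tag one of `"green"`, `"red"`, `"blue"`, `"L"`, `"Y"`,
#'   `"S"`, or `"synthetic"` for rasters built in code.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(intensities, channel_tag = "synthetic") {
  if (!is.matrix(intensities)) stop_input("gray_image: intensities must be a matrix")
  if (any(intensities < -1e-9 | intensities > 1 + 1e-9, na.rm = TRUE))
    stop_input("gray_image: intensities outside [0, 1]")
  structure(list(intensities = clamp(intensities, 0, 1),
                 channel_tag = channel_tag),
            class = "gray_image")
}

#' Binary pixel-label mask
#'
#' @param labels integer matrix of 0/1 (any nonzero value is coerced to 1).
#' @param meaning `"lesion"` or `"optic_disc"`.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(labels, meaning = c("lesion", "optic_disc")) {
  meaning <- match.arg(meaning)
  if (!is.matrix(labels)) stop_input("binary_mask: labels must be a matrix")
  lab <- matrix(as.integer(labels != 0), nrow(labels), ncol(labels))
  structure(list(labels = lab, meaning = meaning), class = "binary_mask")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d, 8-bit RGB, source: %s>\n", d[1], d[2], x$path))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, channel %s, range [%.4f, %.4f]>\n",
              nrow(x$intensities), ncol(x$intensities), x$channel_tag,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, meaning %s, %d positive pixels>\n",
              nrow(x$labels), ncol(x$labels), x$meaning, sum(x$labels)))
  invisible(x)
}

decode_image_file <- function(path) {
  if (!file.exists(path)) stop_input("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext %in% c("jpg", "jpeg")) {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop_input("JPEG support requires the 'jpeg' package: ", path)
      jpeg::readJPEG(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e) stop_input("unreadable image file ", path, ": ",
                                    conditionMessage(e)))
  arr
}

#' Load a color fundus image
#'
#' Reads a PNG or JPEG file into an 8-bit RGB raster. 16-bit PNG samples are
#' rescaled to the 8-bit range (division by 257, rounded). A single-channel
#' input is replicated to three channels with a warning; an alpha channel is
#' dropped.
#'
#' @param path file path to a PNG or JPEG image.
#' @return an [rgb_image].
#' @export
load_rgb <- function(path) {
  arr <- decode_image_file(path)
  if (is.matrix(arr)) {
    warning("single-channel input replicated to 3 channels: ", path)
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  }
  if (dim(arr)[3] == 2L) {  # gray + alpha
    warning("single-channel input replicated to 3 channels: ", path)
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  }
  if (dim(arr)[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  # decoders return [0,1]; for 16-bit sources v/65535 * 255 == v/257 exactly
  rgb_image(rhu(arr * 255), path = path)
}

# Row of the sRGB -> XYZ (D65) matrix; RGB treated as linear (no companding),
# only relative contrast matters downstream.
.xyz_m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                   0.2126729, 0.7151522, 0.0721750,
                   0.0193339, 0.1191920, 0.9503041),
                 nrow = 3, byrow = TRUE)

#' Extract the working intensity channel
#'
#' Pulls one channel out of an RGB fundus image. The green channel carries
#' the highest lesion/background contrast in fundus photography and is the
#' default working channel; L (of CIELAB), Y (of XYZ) and S (of HSI) are
#' provided as alternatives. Derived channels use the standard color-space
#' formulas on linear RGB and are linearly rescaled to `[0, 1]`.
#'
#' @param img an [rgb_image].
#' @param channel_tag one of `"green"`, `"red"`, `"blue"`, `"L"`, `"Y"`, `"S"`.
#' @return a [gray_image], un-normalized (see [normalize_gray]).
#' @export
extract_channel <- function(img, channel_tag = "green") {
  stopifnot(inherits(img, "rgb_image"))
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  r <- matrix(img$pixels[, , 1], h, w) / 255
  g <- matrix(img$pixels[, , 2], h, w) / 255
  b <- matrix(img$pixels[, , 3], h, w) / 255
  v <- switch(channel_tag,
    red   = r,
    green = g,
    blue  = b,
    Y     = .xyz_m[2, 1] * r + .xyz_m[2, 2] * g + .xyz_m[2, 3] * b,
    L     = {
      y <- .xyz_m[2, 1] * r + .xyz_m[2, 2] * g + .xyz_m[2, 3] * b
      d <- 6 / 29
      f <- ifelse(y > d^3, y^(1 / 3), y / (3 * d^2) + 4 / 29)
      (116 * f - 16) / 100
    },
    S     = {
      s <- r + g + b
      out <- 1 - 3 * pmin(r, pmin(g, b)) / ifelse(s > 0, s, 1)
      out[s == 0] <- 0
      out
    },
    stop_config("unknown channel tag '", channel_tag,
                "'; supported: green, red, blue, L, Y, S")
  )
  gray_image(clamp(v, 0, 1), channel_tag = channel_tag)
}

#' Min-max normalize an intensity image
#'
#' Rescales intensities so that the minimum maps to 0 and the maximum to 1.
#' A constant image maps to all zeros (with a warning): no intensity changes
#' exist, so downstream detection is correctly empty.
#'
#' @param img a [gray_image].
#' @return a [gray_image] with `min = 0`, `max = 1` (unless constant).
#' @export
normalize_gray <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  x <- img$intensities
  rng <- range(x)
  if (rng[2] - rng[1] <= .Machine$double.eps) {
    warning("constant image: normalized to all zeros")
    x[] <- 0
  } else {
    x <- (x - rng[1]) / (rng[2] - rng[1])
  }
  gray_image(x, channel_tag = img$channel_tag)
}

#' Read a binary mask from PNG
#'
#' Any nonzero pixel reads as 1. A companion image may be declared to assert
#' the shapes agree.
#'
#' @param path PNG file path.
#' @param meaning `"lesion"` or `"optic_disc"`.
#' @param companion optional [gray_image] or [rgb_image] whose shape the mask
#'   must match.
#' @return a [binary_mask].
#' @export
read_mask <- function(path, meaning = "lesion", companion = NULL) {
  arr <- decode_image_file(path)
  if (!is.matrix(arr)) arr <- arr[, , 1]
  m <- binary_mask(matrix(as.integer(arr > 0), nrow(arr), ncol(arr)),
                   meaning = meaning)
  if (!is.null(companion)) {
    sh <- if (inherits(companion, "rgb_image")) dim(companion$pixels)[1:2]
          else dim(companion$intensities)
    if (!identical(as.integer(dim(m$labels)), as.integer(sh)))
      stop_input("mask shape ", paste(dim(m$labels), collapse = "x"),
                 " does not match companion image ", paste(sh, collapse = "x"))
  }
  m
}

#' Write a binary mask as PNG
#'
#' Foreground is written as 255, background as 0 (8-bit grayscale PNG), so
#' `read_mask(write_mask(m))` round-trips bit-exactly.
#'
#' @param mask a [binary_mask].
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$labels * 1.0, target = path)
  invisible(path)
}

#' Write an RGB image as PNG
#'
#' @param img an [rgb_image].
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}
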