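# Internal helpers shared across modules.

# Round half away from zero. Unlike base round() (banker's rounding) this is
# translation-invariant for integer shifts: rhu(n + x) == n + rhu(x) for any
# integer n. Polar-to-grid rounding relies on that so that the per-pixel and
# whole-image detection paths agree bit-for-bit.
rhu <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shift a matrix by (dy, dx): out[r, c] = m[r + dy, c + dx], NA outside.
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  r_dst <- max(1L, 1L - dy):min(h, h - dy)
  c_dst <- max(1L, 1L - dx):min(w, w - dx)
  if (length(r_dst) < 1L || length(c_dst) < 1L ||
      r_dst[1] > r_dst[length(r_dst)] || c_dst[1] > c_dst[length(c_dst)]) {
    return(out)
  }
  out[r_dst, c_dst] <- m[r_dst + dy, c_dst + dx, drop = FALSE]
  out
}

stop_input <- function(...) {
  stop(structure(class = c("exuscan_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("exuscan_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
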