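# Patch-based IoU scoring of a detection mask against ground truth.

#' Evaluation protocol parameters
#'
#' The image is tiled into non-overlapping square patches; a ground-truth
#' positive patch counts as a true positive when the intersection-over-union
#' between ground truth and prediction inside the patch exceeds
#' `iou_threshold` (default 0.8, strict `>`).
#'
#' @param patch_size square patch side in pixels (>= 4).
#' @param iou_threshold IoU cutoff in `(0, 1]`.
#' @return an `eval_config` list.
#' @export
eval_config <- function(patch_size = 32L, iou_threshold = 0.8) {
  if (patch_size < 4) stop_config("patch_size must be >= 4")
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop_config("iou_threshold must be in (0, 1]")
  structure(list(patch_size = as.integer(patch_size),
                 iou_threshold = iou_threshold),
            class = "eval_config")
}

#' Tile an image shape into square patches
#'
#' Non-overlapping tiling from the origin; ragged right/bottom patches are
#' kept at reduced size, so the windows cover every pixel exactly once.
#'
#' @param shape integer `c(H, W)`.
#' @param patch_size square patch side (>= 4).
#' @return data.frame with columns `row0`, `row1`, `col0`, `col1`
#'   (inclusive 1-based bounds).
#' @export
patchify <- function(shape, patch_size = 32L) {
  if (patch_size < 4) stop_config("patch_size must be >= 4")
  r0 <- seq(1L, shape[1], by = patch_size)
  c0 <- seq(1L, shape[2], by = patch_size)
  g <- expand.grid(row0 = r0, col0 = c0)
  data.frame(row0 = g$row0,
             row1 = pmin(g$row0 + patch_size - 1L, shape[1]),
             col0 = g$col0,
             col1 = pmin(g$col0 + patch_size - 1L, shape[2]))
}

#' Intersection over union of two mask windows
#'
#' `|gt & pred| / |gt | pred|`; defined as 1 when both windows are empty
#' (that convention only ever meets the true-negative branch of
#' [evaluate_masks], so it never affects scores).
#'
#' @param gt_patch,pred_patch 0/1 matrices of identical shape.
#' @return IoU in `[0, 1]`.
#' @export
patch_iou <- function(gt_patch, pred_patch) {
  stopifnot(identical(dim(gt_patch), dim(pred_patch)))
  uni <- sum(gt_patch != 0 | pred_patch != 0)
  if (uni == 0) return(1)
  sum(gt_patch != 0 & pred_patch != 0) / uni
}

#' Patch-level evaluation of a detection mask
#'
#' Every patch with at least one ground-truth pixel is a positive patch; it
#' is a true positive when its IoU exceeds the threshold, else a false
#' negative. A ground-truth-negative patch is a true negative when the
#' prediction is empty there, else a false positive. Sensitivity is
#' `tp / (tp + fn)`, specificity `tn / (tn + fp)`; either is `NA` (flagged)
#' when its denominator is zero.
#'
#' @param gt,pred [binary_mask] objects of identical shape.
#' @param cfg an [eval_config].
#' @return an `eval_report`: counts `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, the config, and a `per_patch` data.frame.
#' @export
evaluate_masks <- function(gt, pred, cfg = eval_config()) {
  stopifnot(inherits(gt, "binary_mask"), inherits(pred, "binary_mask"))
  if (!identical(dim(gt$labels), dim(pred$labels)))
    stop_input("ground truth and prediction shapes differ")
  pw <- patchify(dim(gt$labels), cfg$patch_size)
  pw$gt_positive <- FALSE; pw$pred_positive <- FALSE; pw$iou <- NA_real_
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_len(nrow(pw))) {
    gwin <- gt$labels[pw$row0[k]:pw$row1[k], pw$col0[k]:pw$col1[k], drop = FALSE]
    pwin <- pred$labels[pw$row0[k]:pw$row1[k], pw$col0[k]:pw$col1[k], drop = FALSE]
    pw$gt_positive[k] <- any(gwin == 1L)
    pw$pred_positive[k] <- any(pwin == 1L)
    pw$iou[k] <- patch_iou(gwin, pwin)
    if (pw$gt_positive[k]) {
      if (pw$iou[k] > cfg$iou_threshold) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pw$pred_positive[k]) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 undefined_sensitivity = tp + fn == 0,
                 undefined_specificity = tn + fp == 0,
                 config = cfg, per_patch = pw),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report patches=%d tp=%d fp=%d tn=%d fn=%d sens=%.4f spec=%.4f>\n",
              nrow(x$per_patch), x$tp, x$fp, x$tn, x$fn,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' One-line TSV summary of an evaluation report
#'
#' @param report an `eval_report`.
#' @param header include the column-name line.
#' @return character vector of TSV lines.
#' @export
report_tsv <- function(report, header = TRUE) {
  line <- paste(report$config$patch_size, report$config$iou_threshold,
                report$tp, report$fp, report$tn, report$fn,
                format(report$sensitivity), format(report$specificity),
                sep = "\t")
  if (header)
    c(paste("patch_size", "iou_threshold", "tp", "fp", "tn", "fn",
            "sensitivity", "specificity", sep = "\t"), line)
  else line
}

#' JSON-ready list form of an evaluation report
#'
#' @param report an `eval_report`.
#' @param per_patch include the per-patch table.
#' @return a plain list suitable for `jsonlite::write_json`.
#' @export
report_json <- function(report, per_patch = FALSE) {
  out <- list(patch_size = report$config$patch_size,
              iou_threshold = report$config$iou_threshold,
              tp = report$tp, fp = report$fp, tn = report$tn, fn = report$fn,
              sensitivity = report$sensitivity,
              specificity = report$specificity)
  if (per_patch) out$per_patch <- report$per_patch
  out
}
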