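# Downstream use of QC masks: exclude artifact pixels from scoring, corrupt
# regions with synthetic out-of-focus, quantify the accuracy effect, and
# filter point detections.

#' Mask artifact pixels of a patch before downstream analysis
#'
#' Pixels whose artifact-mask label is an artifact class (anything other than
#' background or artifact-free tissue) are filled white (`fill_policy =
#' "white"`) or only flagged (`"ignore_label"`); non-artifact pixels are
#' untouched bit-for-bit. Downstream scoring must exclude the flagged pixels
#' — masking prevents misclassification in corrupted areas, it cannot recover
#' structures there.
#'
#' @param patch A [qc_raster].
#' @param artifact_mask Artifact-scheme `qc_mask` (resampled to the patch
#'   dims if needed).
#' @param fill_policy `"white"` or `"ignore_label"`.
#' @return List: `patch` (a `qc_raster`) and `ignore` (logical matrix of
#'   pixels to exclude from scoring).
#' @export
apply_qc_mask <- function(patch, artifact_mask,
                          fill_policy = c("white", "ignore_label")) {
  fill_policy <- match.arg(fill_policy)
  stop_if_not(inherits(patch, "qc_raster"), "patch must be a qc_raster")
  stop_if_not(inherits(artifact_mask, "qc_mask") &&
              artifact_mask$scheme$kind == "artifact",
              "artifact_mask must be an artifact-scheme qc_mask",
              class = "slideqc_scheme_error")
  h <- raster_h(patch); w <- raster_w(patch)
  lab <- resize_nearest(artifact_mask$labels, h, w)
  ignore <- lab > class_index(artifact_mask$scheme, "tissue_no_artifact")
  px <- patch$pixels
  if (fill_policy == "white" && any(ignore)) {
    for (ch in 1:3) {
      v <- px[, , ch]; v[ignore] <- 1; px[, , ch] <- v
    }
  }
  list(patch = qc_raster(px, patch$mpp), ignore = ignore)
}

#' Corrupt a region of interest with synthetic out-of-focus
#'
#' Delegates to [inject_oof]: Gaussian blur under a random smooth binary map
#' covering at least `min_frac` of the region, with the kernel size drawn
#' from `kernel_sizes`. The ground truth records the corrupted region for
#' scoring.
#'
#' @param roi A `qc_labeled_slide`.
#' @param min_frac Minimum out-of-focus fraction (default 0.30).
#' @param kernel_sizes Odd Gaussian kernel sizes (default 3 to 17).
#' @param seed Integer seed.
#' @return The corrupted `qc_labeled_slide` (with the binary map in
#'   `attr(, "oof_map")`).
#' @export
corrupt_roi_with_oof <- function(roi, min_frac = 0.30,
                                 kernel_sizes = seq(3L, 17L, 2L), seed = 1L) {
  inject_oof(roi, oof_spec(min_frac = min_frac, kernel_sizes = kernel_sizes,
                           seed = seed))
}

# one-vs-rest sensitivity/specificity per class, excluding ignored pixels
class_sens_spec <- function(pred, gt, ignore = NULL) {
  keep <- if (is.null(ignore)) rep(TRUE, length(gt$labels)) else !as.vector(ignore)
  p <- as.vector(pred$labels)[keep]; g <- as.vector(gt$labels)[keep]
  k <- n_classes(gt$scheme)
  out <- data.frame(class = gt$scheme$names, dice = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  for (c in seq_len(k) - 1L) {
    tp <- sum(p == c & g == c); fn <- sum(p != c & g == c)
    fp <- sum(p == c & g != c); tn <- sum(p != c & g != c)
    if (tp + fn + fp > 0) out$dice[c + 1] <- 2 * tp / (2 * tp + fp + fn)
    if (tp + fn > 0) out$sensitivity[c + 1] <- tp / (tp + fn)
    if (tn + fp > 0) out$specificity[c + 1] <- tn / (tn + fp)
  }
  out
}

#' Accuracy effect of corruption and QC masking
#'
#' Scores three conditions of a downstream segmentation against the same
#' ground truth: `baseline` (clean input), `corrupted` (no QC) and
#' `corrected` (QC-masked input, scored with artifact pixels excluded via
#' the ignore mask). Reports per-class Dice, sensitivity and specificity
#' (one-vs-rest).
#'
#' @param gt Ground-truth `qc_mask`.
#' @param pred_baseline,pred_corrupted,pred_corrected Predicted `qc_mask`s of
#'   the same dims and scheme.
#' @param ignore Logical matrix of pixels excluded when scoring the corrected
#'   condition (from [apply_qc_mask]).
#' @return Data frame with columns `condition`, `class`, `dice`,
#'   `sensitivity`, `specificity`.
#' @export
accuracy_delta <- function(gt, pred_baseline, pred_corrupted, pred_corrected,
                           ignore) {
  for (m in list(pred_baseline, pred_corrupted, pred_corrected)) check_pair(m, gt)
  stop_if_not(all(dim(ignore) == dim(gt$labels)),
              "ignore mask dims differ from gt", class = "slideqc_shape_error")
  rows <- rbind(
    cbind(condition = "baseline", class_sens_spec(pred_baseline, gt)),
    cbind(condition = "corrupted", class_sens_spec(pred_corrupted, gt)),
    cbind(condition = "corrected", class_sens_spec(pred_corrected, gt, ignore)))
  rows
}

#' Point detections bound to an MPP
#'
#' @param x,y Point coordinates in pixels (0-based) at `mpp`.
#' @param class Class label per point.
#' @param mpp Microns per pixel of the coordinate frame.
#' @return Object of class `qc_detections` (data frame `x`, `y`, `class`
#'   with an `mpp` attribute).
#' @export
detection_set <- function(x = numeric(0), y = numeric(0),
                          class = character(length(x)), mpp = 1.0) {
  stop_if_not(length(x) == length(y) && length(x) == length(class),
              "x, y and class must have equal length")
  structure(data.frame(x = x, y = y, class = class), mpp = mpp,
            class = c("qc_detections", "data.frame"))
}

#' Remove detections falling on artifact pixels
#'
#' Membership uses each detection's centre point looked up in the artifact
#' mask (coordinates are rescaled to the mask's MPP first). Points on
#' artifact-class pixels are removed; order is preserved. Out-of-extent
#' points are dropped with a message.
#'
#' @param dets A [detection_set].
#' @param artifact_mask Artifact-scheme `qc_mask`.
#' @return The filtered [detection_set].
#' @export
filter_detections <- function(dets, artifact_mask) {
  stop_if_not(inherits(dets, "qc_detections"), "dets must be a detection_set")
  stop_if_not(inherits(artifact_mask, "qc_mask") &&
              artifact_mask$scheme$kind == "artifact",
              "artifact_mask must be an artifact-scheme qc_mask",
              class = "slideqc_scheme_error")
  if (nrow(dets) == 0) return(dets)
  s <- attr(dets, "mpp") / artifact_mask$mpp
  cx <- floor(dets$x * s); cy <- floor(dets$y * s)
  h <- nrow(artifact_mask$labels); w <- ncol(artifact_mask$labels)
  inb <- cx >= 0 & cy >= 0 & cx < w & cy < h
  if (any(!inb))
    message(sum(!inb), " detection(s) outside the mask extent dropped")
  lab <- rep(0L, nrow(dets))
  lab[inb] <- artifact_mask$labels[cbind(cy[inb] + 1L, cx[inb] + 1L)]
  keep <- inb & lab <= class_index(artifact_mask$scheme, "tissue_no_artifact")
  out <- dets[keep, , drop = FALSE]
  attr(out, "mpp") <- attr(dets, "mpp")
  class(out) <- c("qc_detections", "data.frame")
  rownames(out) <- NULL
  out
}

#' Read/write detections as CSV
#' @param dets A [detection_set].
#' @param path CSV path.
#' @return `path` (write) or a [detection_set] (read).
#' @export
write_detections <- function(dets, path) {
  df <- as.data.frame(dets)
  df$mpp <- attr(dets, "mpp")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  detection_set(df$x, df$y, df$class, mpp = df$mpp[1] %||% 1.0)
}
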