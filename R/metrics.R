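# Segmentation accuracy metrics: per-class Dice, confusion matrices and
# row-normalised misclassification-pattern tables.

check_pair <- function(pred, gt) {
  stop_if_not(inherits(pred, "qc_mask") && inherits(gt, "qc_mask"),
              "pred and gt must be qc_mask")
  stop_if_not(all(dim(pred$labels) == dim(gt$labels)),
              "pred and gt dims differ", class = "slideqc_shape_error")
  stop_if_not(same_scheme(pred$scheme, gt$scheme),
              "pred and gt schemes differ", class = "slideqc_scheme_error")
}

#' Per-class Dice score of a predicted mask against ground truth
#'
#' `Dice_c = 2 |P_c  G_c| / (|P_c| + |G_c|)`. Classes absent from both
#' masks are undefined (`NA`) and excluded from the mean.
#'
#' @param pred,gt `qc_mask` objects of equal dims and scheme.
#' @return List with `per_class` (named vector, `NA` where undefined) and
#'   `mean` over the defined classes.
#' @export
dice_per_class <- function(pred, gt) {
  check_pair(pred, gt)
  cm <- confusion_matrix(pred, gt)
  dice_from_confusion(cm)
}

# shared core: Dice from a confusion matrix (rows gt, cols pred)
dice_from_confusion <- function(cm) {
  counts <- cm$counts
  k <- nrow(counts)
  p <- colSums(counts); g <- rowSums(counts)
  d <- ifelse(p + g > 0, 2 * diag(counts) / (p + g), NA_real_)
  names(d) <- cm$scheme$names
  list(per_class = d, mean = mean(d, na.rm = TRUE))
}

#' Pixel-level confusion matrix
#'
#' @param pred,gt `qc_mask` objects of equal dims and scheme.
#' @return Object of class `qc_confusion`: `counts` (K x K integer matrix,
#'   rows = ground-truth class, cols = predicted class) and `scheme`.
#' @export
confusion_matrix <- function(pred, gt) {
  check_pair(pred, gt)
  k <- n_classes(gt$scheme)
  idx <- as.vector(gt$labels) * k + as.vector(pred$labels) + 1L
  counts <- matrix(tabulate(idx, nbins = k * k), k, k, byrow = TRUE,
                   dimnames = list(gt = gt$scheme$names, pred = gt$scheme$names))
  structure(list(counts = counts, scheme = gt$scheme), class = "qc_confusion")
}

#' @export
print.qc_confusion <- function(x, ...) {
  cat("<qc_confusion> rows = ground truth, cols = prediction\n")
  print(x$counts)
  invisible(x)
}

#' Row-normalised misclassification-pattern table
#'
#' Each reported row gives, for one ground-truth class, the percentage of its
#' pixels predicted as each class; rows sum to 100. Ground-truth classes with
#' no pixels are omitted and listed in the `omitted` attribute.
#'
#' @param cm A `qc_confusion`.
#' @return Numeric matrix of percentages (rows = reported ground-truth
#'   classes), with attribute `omitted` naming any zero-pixel classes.
#' @export
misclassification_table <- function(cm) {
  stop_if_not(inherits(cm, "qc_confusion"), "cm must be a qc_confusion")
  rs <- rowSums(cm$counts)
  keep <- rs > 0
  out <- 100 * cm$counts[keep, , drop = FALSE] / rs[keep]
  attr(out, "omitted") <- rownames(cm$counts)[!keep]
  out
}

#' Evaluate a model over a labeled dataset (pooled pixels)
#'
#' Predicts every patch, pools all pixels into one confusion matrix and
#' reports one Dice score per class, plus the mean over defined classes —
#' micro-averaged, so the result equals Dice on the concatenation of all
#' masks. `macro = TRUE` instead averages per-patch Dice scores.
#'
#' @param bundle A trained `qc_model_bundle`.
#' @param pairs List of `qc_labeled_slide` matching the bundle's scheme and
#'   patch size.
#' @param macro Use per-patch (macro) averaging instead of pooling.
#' @return List: `dice` (named per-class vector), `mean`, `confusion`
#'   (pooled `qc_confusion`; `NULL` for macro).
#' @export
evaluate_dataset <- function(bundle, pairs, macro = FALSE) {
  stop_if_not(length(pairs) >= 1, "empty evaluation set", class = "slideqc_data_error")
  preds <- predict(bundle, lapply(pairs, function(p) p$image))
  if (!macro) {
    k <- n_classes(bundle$config$scheme)
    total <- matrix(0, k, k)
    for (i in seq_along(pairs)) {
      cmi <- confusion_matrix(preds[[i]]$mask, pairs[[i]]$gt)
      total <- total + cmi$counts
    }
    dimnames(total) <- list(gt = bundle$config$scheme$names,
                            pred = bundle$config$scheme$names)
    cm <- structure(list(counts = total, scheme = bundle$config$scheme),
                    class = "qc_confusion")
    d <- dice_from_confusion(cm)
    list(dice = d$per_class, mean = d$mean, confusion = cm)
  } else {
    per <- vapply(seq_along(pairs), function(i)
      dice_per_class(preds[[i]]$mask, pairs[[i]]$gt)$per_class,
      numeric(n_classes(bundle$config$scheme)))
    d <- rowMeans(per, na.rm = TRUE)
    list(dice = d, mean = mean(d, na.rm = TRUE), confusion = NULL)
  }
}
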