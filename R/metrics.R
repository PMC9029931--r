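# The eight-metric evaluation suite: pixel accuracy, Dice, IoU, precision,
# recall, under-/over-segmentation rates (FNR/FPR) and Hausdorff distance,
# all derived from per-image confusion counts.

#' Pixel confusion tensor
#'
#' Counts `P[i, j]` = number of pixels with true class `i` predicted as class
#' `j` (classes `0..C-1`; row 1 is class 0).
#'
#' @param pred,truth Integer label maps (same shape), values in `0..C-1`.
#' @param num_classes Number of classes `C`.
#' @return A `C x C` integer matrix of class `confusion_tensor` with
#'   dimnames giving the class indices.
#' @export
confusion_tensor <- function(pred, truth, num_classes = 4L) {
  if (length(pred) != length(truth)) abort("`pred` and `truth` differ in size")
  P <- confusion_counts(as.integer(truth), as.integer(pred), as.integer(num_classes))
  dimnames(P) <- list(true = 0:(num_classes - 1), pred = 0:(num_classes - 1))
  class(P) <- c("confusion_tensor", class(P))
  P
}

#' Scalar metrics from a confusion tensor
#'
#' Per class `c`: `TP = P[c,c]`, `FN` = rest of row `c`, `FP` = rest of
#' column `c`, `TN` = remainder. Dice `= 2TP/(2TP+FP+FN)`, IoU
#' `= TP/(TP+FP+FN)`, precision `= TP/(TP+FP)`, recall `= TP/(TP+FN)`,
#' FNR `= FN/(FN+TP)` (under-segmentation), FPR `= FP/(FP+TN)`
#' (over-segmentation). Accuracy is global: trace over total, always
#' background-inclusive. Ratios with empty denominators are `NA` and are
#' excluded from macro averages.
#'
#' @param tensor A [confusion_tensor()].
#' @param average_classes Classes entering the macro averages; default the
#'   three chromosome classes `1:3`, use `0:3` for background-inclusive
#'   averaging.
#' @return A `metric_report` list with `per_class` (tibble), `accuracy`, and
#'   `averages` (named vector).
#' @export
scalar_metrics <- function(tensor, average_classes = 1:3) {
  C <- nrow(tensor)
  total <- sum(tensor)
  if (total == 0) abort("empty confusion tensor")
  tp <- diag(tensor)
  fn <- rowSums(tensor) - tp
  fp <- colSums(tensor) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  per_class <- tibble(
    class = 0:(C - 1),
    tp = as.numeric(tp), fp = as.numeric(fp),
    fn = as.numeric(fn), tn = as.numeric(tn),
    dice = safe_div(2 * tp, 2 * tp + fp + fn),
    iou = safe_div(tp, tp + fp + fn),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    fnr = safe_div(fn, fn + tp),
    fpr = safe_div(fp, fp + tn)
  )
  sel <- per_class$class %in% average_classes
  avg <- vapply(c("dice", "iou", "precision", "recall", "fnr", "fpr"),
                function(m) mean(per_class[[m]][sel], na.rm = TRUE), numeric(1))
  structure(list(per_class = per_class,
                 accuracy = sum(tp) / total,
                 averages = avg,
                 average_classes = average_classes),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy %.4f; macro over classes {%s}:\n",
              x$accuracy, paste(x$average_classes, collapse = ",")))
  print(round(x$averages, 4))
  invisible(x)
}

#' Symmetric Hausdorff distance between two binary masks
#'
#' Maximum over the two directed sup-inf Euclidean distances between the
#' pixel-coordinate sets of the masks. Both masks empty gives 0; exactly one
#' empty returns the image diagonal `sqrt(H^2 + W^2)` as a finite penalty.
#'
#' @param mask_pred,mask_true Logical/0-1 matrices on the same grid.
#' @return Distance in pixels (>= 0, 0 iff the sets coincide).
#' @export
hausdorff_distance <- function(mask_pred, mask_true) {
  if (!all(dim(mask_pred) == dim(mask_true))) abort("masks differ in shape")
  A <- which(mask_pred != 0, arr.ind = TRUE)
  B <- which(mask_true != 0, arr.ind = TRUE)
  if (nrow(A) == 0 && nrow(B) == 0) return(0)
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(sqrt(sum(dim(mask_true)^2)))
  }
  hausdorff_points(A * 1.0, B * 1.0)
}

#' Evaluate one predicted label map against the ground truth
#'
#' Computes the confusion-based scalar metrics plus the per-class Hausdorff
#' distance, macro-averaged over the evaluated classes. Classes absent from
#' both maps are skipped.
#'
#' @param pred,truth Integer label maps `0..C-1`, same shape.
#' @param num_classes Number of classes.
#' @param average_classes Classes entering macro averages (default `1:3`).
#' @return One-row tibble with columns `acc`, `dice`, `iou`, `precision`,
#'   `recall`, `fnr`, `fpr`, `hausdorff`.
#' @export
evaluate_image <- function(pred, truth, num_classes = 4L, average_classes = 1:3) {
  ct <- confusion_tensor(pred, truth, num_classes)
  rep_ <- scalar_metrics(ct, average_classes)
  hd <- vapply(average_classes, function(cc) {
    pm <- pred == cc
    tm <- truth == cc
    if (!any(pm) && !any(tm)) return(NA_real_)
    hausdorff_distance(pm, tm)
  }, numeric(1))
  tibble(
    acc = rep_$accuracy,
    dice = rep_$averages[["dice"]],
    iou = rep_$averages[["iou"]],
    precision = rep_$averages[["precision"]],
    recall = rep_$averages[["recall"]],
    fnr = rep_$averages[["fnr"]],
    fpr = rep_$averages[["fpr"]],
    hausdorff = mean(hd, na.rm = TRUE)
  )
}

#' Row-normalized confusion percentages
#'
#' Normalizes each true-class row of a confusion tensor to percentages, the
#' layout used for confusion-matrix reporting.
#'
#' @param tensor A [confusion_tensor()].
#' @return Numeric matrix of row percentages (rows summing to 100 where the
#'   class occurs).
#' @export
confusion_percent <- function(tensor) {
  rs <- rowSums(tensor)
  sweep(unclass(tensor) * 100, 1, pmax(rs, 1), "/")
}

#' @rdname confusion_tensor
#' @param x A `confusion_tensor`.
#' @param ... Unused.
#' @method tidy confusion_tensor
#' @export
tidy.confusion_tensor <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "pixels")) |>
    mutate(true = as.integer(as.character(.data$true)),
           pred = as.integer(as.character(.data$pred)))
}

#' @rdname scalar_metrics
#' @param x A `metric_report`.
#' @param ... Unused.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' @rdname scalar_metrics
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, !!!as.list(x$averages))
}
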