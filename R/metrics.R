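#' Binary cross-entropy loss on probability maps
#'
#' Per-pixel mean of `-(A log B + (1 - A) log(1 - B))` with ground truth `A`
#' and predicted probability `B`. Probabilities are clamped to
#' `[eps, 1 - eps]` so the loss stays finite at saturated predictions.
#'
#' @param gt binary array/matrix/vector (values in {0, 1}).
#' @param pred numeric array of the same dimensions with values in [0, 1].
#' @param eps clamp applied to `pred` before taking logs.
#' @return Non-negative scalar loss.
#' @examples
#' bce_loss(c(1, 0), c(0.9, 0.2))  # -(log(0.9) + log(0.8)) / 2
#' @export
bce_loss <- function(gt, pred, eps = 1e-7) {
  check_pair(gt, pred)
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  a <- as.numeric(gt)
  -mean(a * log(p) + (1 - a) * log1p(-p))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(A * B) + smooth) / (sum(A) + sum(B) + smooth)`. The smooth
#' term (default 1) keeps the ratio defined when both masks are empty, so a
#' correctly predicted all-background image has zero loss. With a soft
#' prediction the intersection is the elementwise product, which reduces to
#' set intersection on binary inputs.
#'
#' @inheritParams bce_loss
#' @param smooth additive smoothing constant in numerator and denominator.
#' @return Loss in [0, 1).
#' @examples
#' dice_loss(matrix(0, 4, 4), matrix(0, 4, 4))  # 0: doubly-empty case
#' @export
dice_loss <- function(gt, pred, smooth = 1) {
  check_pair(gt, pred)
  a <- as.numeric(gt)
  b <- as.numeric(pred)
  1 - (2 * sum(a * b) + smooth) / (sum(a) + sum(b) + smooth)
}

#' Compound training loss: BCE + Dice
#'
#' The sum of [bce_loss()] and [dice_loss()], combining the per-pixel
#' (microscopic) cross-entropy signal with the global overlap measure.
#'
#' @inheritParams dice_loss
#' @param eps clamp for the BCE term.
#' @return Scalar loss.
#' @export
total_loss <- function(gt, pred, smooth = 1, eps = 1e-7) {
  bce_loss(gt, pred, eps = eps) + dice_loss(gt, pred, smooth = smooth)
}

check_pair <- function(gt, pred) {
  dg <- dim(gt) %||% length(gt)
  dp <- dim(pred) %||% length(pred)
  if (!identical(as.integer(dg), as.integer(dp))) {
    stop("ground truth and prediction dimensions differ", call. = FALSE)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixel confusion counts between two binary masks
#'
#' @param gt binary ground-truth mask.
#' @param pred_mask binary predicted mask (probabilities should be
#'   thresholded at 0.5 beforehand; see [binarize()]).
#' @return Object of class `confusion_counts`: list with integer `TP`, `FP`,
#'   `FN`, `TN` summing to the pixel count.
#' @export
confusion <- function(gt, pred_mask) {
  check_pair(gt, pred_mask)
  a <- as.numeric(gt) > 0.5
  b <- as.numeric(pred_mask) > 0.5
  structure(list(TP = sum(a & b), FP = sum(!a & b),
                 FN = sum(a & !b), TN = sum(!a & !b)),
            class = "confusion_counts")
}

#' Threshold a probability map into a binary mask
#'
#' @param pred numeric probability array.
#' @param threshold decision threshold (default 0.5).
#' @return Array of 0/1 values with `pred`'s dimensions.
#' @export
binarize <- function(pred, threshold = 0.5) {
  out <- (pred >= threshold) * 1
  dim(out) <- dim(pred)
  out
}

#' Per-image segmentation metrics from confusion counts
#'
#' Computes pixel accuracy, intersection-over-union, Dice, precision and
#' recall:
#' \itemize{
#'   \item `acc = (TP + TN) / (TP + TN + FP + FN)`
#'   \item `iou = TP / (TP + FP + FN)`
#'   \item `dice = (2 TP + smooth) / (2 TP + FP + FN + smooth)`
#'   \item `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`
#' }
#' Zero-denominator convention for iou/precision/recall: when both masks are
#' empty (the image truly has no lesion and none was predicted) the metric is
#' 1; when one side is empty and the other is not, it is 0. Dice follows the
#' smoothed form, so the doubly-empty case is 1 by construction; passing
#' `smooth = 0` recovers the raw ratio `2 IoU / (1 + IoU)` on non-empty
#' masks.
#'
#' @param counts a `confusion_counts` object (or list with TP/FP/FN/TN).
#' @param smooth smoothing constant of the Dice ratio (default 1).
#' @return Named numeric vector (`acc`, `iou`, `dice`, `precision`,
#'   `recall`), all fractions in [0, 1].
#' @examples
#' metrics_from_counts(confusion(matrix(0, 2, 2), matrix(0, 2, 2)))
#' @export
metrics_from_counts <- function(counts, smooth = 1) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  safe <- function(num, den) {
    if (den == 0) {
      # denominator empty means neither mask marks any pixel -> perfect match
      return(1)
    }
    num / den
  }
  acc <- safe(tp + tn, tp + tn + fp + fn)
  iou <- safe(tp, tp + fp + fn)
  dice <- if (smooth > 0) {
    (2 * tp + smooth) / (2 * tp + fp + fn + smooth)
  } else {
    safe(2 * tp, 2 * tp + fp + fn)
  }
  pr <- safe(tp, tp + fp)
  re <- safe(tp, tp + fn)
  # one-sided empties (lesion missed entirely, or predicted where none is):
  # every overlap metric is 0, including the 0/0 ratios
  if (tp == 0 && (fp + fn) > 0) {
    iou <- 0
    pr <- 0
    re <- 0
  }
  c(acc = acc, iou = iou, dice = dice, precision = pr, recall = re)
}

#' Dataset-mean metric report
#'
#' Averages per-image metric tuples over a test set; the `m` prefix of
#' mAcc/mIoU/mDice/mPr/mRe denotes exactly this arithmetic mean.
#'
#' @param per_image a data.frame (or list of named vectors) with columns
#'   `acc`, `iou`, `dice`, `precision`, `recall`.
#' @return Named numeric vector of means, class `metric_report`.
#' @export
mean_metrics <- function(per_image) {
  if (is.list(per_image) && !is.data.frame(per_image)) {
    per_image <- as.data.frame(do.call(rbind, per_image))
  }
  if (NROW(per_image) == 0) stop("no per-image metrics to average", call. = FALSE)
  cols <- c("acc", "iou", "dice", "precision", "recall")
  stopifnot(all(cols %in% names(per_image)))
  structure(colMeans(per_image[cols]), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric report (dataset means, %)>\n")
  lab <- c(acc = "mAcc", iou = "mIoU", dice = "mDice",
           precision = "mPr", recall = "mRe")
  for (k in names(lab)) {
    cat(sprintf("  %-6s %6.2f\n", lab[[k]], 100 * unclass(x)[[k]]))
  }
  invisible(x)
}

#' Write per-image metrics and a summary row to CSV
#'
#' Percentages with two decimals, one row per image plus a final `mean` row.
#'
#' @param per_image data.frame with an `id` column and metric columns.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics_csv <- function(per_image, path) {
  cols <- c("acc", "iou", "dice", "precision", "recall")
  stopifnot(is.data.frame(per_image), all(c("id", cols) %in% names(per_image)))
  out <- per_image[c("id", cols)]
  means <- colMeans(out[cols])
  out[cols] <- lapply(out[cols], function(v) sprintf("%.2f", 100 * v))
  summary_row <- data.frame(id = "mean",
                            t(vapply(means, function(v) sprintf("%.2f", 100 * v),
                                     character(1))))
  names(summary_row) <- names(out)
  utils::write.csv(rbind(out, summary_row), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
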