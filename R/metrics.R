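# Pixel-level segmentation metrics from confusion counts.
#
# Conventions: masks are {0,1} grids with 1 = nodule foreground. When a
# metric's denominator is zero it is defined as 1.0 if both masks are empty
# (perfect agreement on "no nodule") and 0.0 otherwise.

check_binary_mask <- function(m, what) {
  if (!all(m %in% c(0, 1)))
    stop("`", what, "` must contain only 0/1 values")
  invisible(m)
}

#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred_mask,gt_mask Binary `{0,1}` grids of identical shape.
#' @return Object of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn`; the four counts always sum to the number of pixels.
#' @examples
#' confusion_counts(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("mask shapes differ: ", paste(dim(pred_mask), collapse = "x"),
         " vs ", paste(dim(gt_mask), collapse = "x"))
  check_binary_mask(pred_mask, "pred_mask")
  check_binary_mask(gt_mask, "gt_mask")
  p <- pred_mask == 1
  g <- gt_mask == 1
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g)),
            class = "confusion_counts")
}

# Shared zero-denominator convention.
.safe_ratio <- function(num, den, c) {
  if (den > 0) return(num / den)
  if (c$tp + c$fp + c$fn == 0) 1.0 else 0.0
}

#' Dice coefficient \code{2TP / (FP + 2TP + FN)}
#' @param c A [confusion_counts()] object.
#' @return Value in `[0, 1]`.
#' @export
dice <- function(c) .safe_ratio(2 * c$tp, c$fp + 2 * c$tp + c$fn, c)

#' Precision \code{TP / (TP + FP)}
#' @inheritParams dice
#' @return Value in `[0, 1]`; 1.0 when nothing is predicted and the
#'   reference is also empty, 0.0 when nothing is predicted but the
#'   reference is not.
#' @export
precision <- function(c) {
  if (c$tp + c$fp > 0) return(c$tp / (c$tp + c$fp))
  if (c$fn == 0) 1.0 else 0.0
}

#' Recall \code{TP / (TP + FN)}
#' @inheritParams dice
#' @return Value in `[0, 1]`; 1.0 when the reference is empty and nothing
#'   is predicted, 0.0 when the reference is empty but pixels are predicted.
#' @export
recall <- function(c) {
  if (c$tp + c$fn > 0) return(c$tp / (c$tp + c$fn))
  if (c$fp == 0) 1.0 else 0.0
}

#' F1 score \code{2 P R / (P + R)}
#'
#' For binary masks the harmonic mean of precision and recall reduces
#' algebraically to \code{2TP / (2TP + FP + FN)}, i.e. the Dice
#' coefficient; it is evaluated in that form so the identity
#' `f1_score(c) == dice(c)` holds exactly, not merely to rounding.
#' @inheritParams dice
#' @return Value in `[0, 1]`.
#' @export
f1_score <- function(c) .safe_ratio(2 * c$tp, c$fp + 2 * c$tp + c$fn, c)

#' Mean intersection-over-union across classes
#'
#' Mean over classes of `TP_i / (FP_i + TP_i + FN_i)`, where the counts of
#' class `i` treat that class as positive. For the binary task the classes
#' are background and nodule.
#'
#' @param per_class_counts Nonempty list of [confusion_counts()], one per
#'   class.
#' @return Value in `[0, 1]`.
#' @export
miou <- function(per_class_counts) {
  if (!is.list(per_class_counts) || !length(per_class_counts))
    stop("`per_class_counts` must be a nonempty list")
  if (inherits(per_class_counts, "confusion_counts"))
    per_class_counts <- list(per_class_counts)
  ious <- vapply(per_class_counts, function(c) {
    stopifnot(inherits(c, "confusion_counts"))
    .safe_ratio(c$tp, c$fp + c$tp + c$fn, c)
  }, numeric(1))
  mean(ious)
}

# Background + foreground confusion counts for a binary pair.
binary_class_counts <- function(pred_mask, gt_mask) {
  list(background = confusion_counts(1 - pred_mask, 1 - gt_mask),
       foreground = confusion_counts(pred_mask, gt_mask))
}

#' All five metrics for one predicted/reference mask pair
#'
#' @inheritParams confusion_counts
#' @return One-row data.frame with columns `dice`, `miou`, `precision`,
#'   `recall`, `f1`.
#' @export
segmentation_metrics <- function(pred_mask, gt_mask) {
  cc <- confusion_counts(pred_mask, gt_mask)
  data.frame(dice = dice(cc),
             miou = miou(binary_class_counts(pred_mask, gt_mask)),
             precision = precision(cc),
             recall = recall(cc),
             f1 = f1_score(cc))
}

#' Precision-recall curve over a threshold grid
#'
#' For each threshold, every probability map is binarized at `prob >=
#' threshold`, confusion counts are pooled over the whole set, and one
#' (recall, precision) point is emitted. At a threshold above every
#' probability no pixel is predicted and precision is reported as 1.0.
#'
#' @param prob_maps List of probability matrices in `[0, 1]`.
#' @param gt_masks List of binary masks, aligned with `prob_maps`.
#' @param thresholds Numeric vector of thresholds; default 101 evenly
#'   spaced values in `[0, 1]`.
#' @return data.frame with columns `threshold`, `recall`, `precision`;
#'   recall is non-increasing in threshold.
#' @export
pr_curve <- function(prob_maps, gt_masks,
                     thresholds = seq(0, 1, length.out = 101L)) {
  if (!is.list(prob_maps)) prob_maps <- list(prob_maps)
  if (!is.list(gt_masks)) gt_masks <- list(gt_masks)
  if (length(prob_maps) != length(gt_masks))
    stop("got ", length(prob_maps), " probability maps but ",
         length(gt_masks), " masks")
  for (i in seq_along(prob_maps))
    if (!identical(dim(prob_maps[[i]]), dim(gt_masks[[i]])))
      stop("shape mismatch at item ", i)
  p_all <- unlist(prob_maps, use.names = FALSE)
  g_all <- unlist(gt_masks, use.names = FALSE) == 1
  n_pos <- sum(g_all)
  out <- data.frame(threshold = thresholds, recall = NA_real_,
                    precision = NA_real_)
  for (i in seq_along(thresholds)) {
    pred <- p_all >= thresholds[i]
    tp <- sum(pred & g_all)
    n_pred <- sum(pred)
    out$recall[i] <- if (n_pos > 0) tp / n_pos else 1.0
    out$precision[i] <- if (n_pred > 0) tp / n_pred else 1.0
  }
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
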