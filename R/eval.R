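#' Dice coefficient between two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`, defined as 1 when both masks are empty (so frames
#' where a chamber is absent from both prediction and reference are not
#' dropped).
#'
#' @param pred_mask,gt_mask binary matrices of the same size.
#' @return value in `[0, 1]`.
#' @export
dice <- function(pred_mask, gt_mask) {
  a <- as_mask(pred_mask, "pred_mask"); b <- as_mask(gt_mask, "gt_mask")
  stopifnot_same_size(a, b, "masks")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Intersection over union (Jaccard index) between two binary masks
#'
#' `|A∩B| / |A∪B|`, defined as 1 when both masks are empty.  Related to the
#' Dice coefficient by `D = 2J / (1 + J)`.
#'
#' @inheritParams dice
#' @return value in `[0, 1]`.
#' @export
iou <- function(pred_mask, gt_mask) {
  a <- as_mask(pred_mask, "pred_mask"); b <- as_mask(gt_mask, "gt_mask")
  stopifnot_same_size(a, b, "masks")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Pixel accuracy of a predicted label map
#'
#' With `class_id = NULL`, the overall fraction of pixels whose predicted
#' label equals the reference label.  With a class id, the recall of that
#' class: correctly labeled class pixels over reference class pixels
#' (1 when the class is absent from the reference).
#'
#' @param pred,gt integer label maps of the same size.
#' @param class_id optional class id (0-4).
#' @return value in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, gt, class_id = NULL) {
  stopifnot(is.matrix(pred), is.matrix(gt))
  stopifnot_same_size(pred, gt, "label maps")
  if (is.null(class_id)) return(mean(pred == gt))
  sel <- gt == class_id
  if (!any(sel)) return(1)
  mean(pred[sel] == class_id)
}

#' Mean pixel accuracy over the classes present in the reference
#'
#' The mean of the per-class pixel accuracies (class recalls, see
#' [pixel_accuracy()]) over all classes present in the reference map,
#' including background.
#'
#' @inheritParams pixel_accuracy
#' @return value in `[0, 1]`.
#' @export
mean_pixel_accuracy <- function(pred, gt) {
  present <- sort(unique(as.vector(gt)))
  mean(vapply(present, function(k) pixel_accuracy(pred, gt, k), numeric(1)))
}

#' Segmentation metrics over a set of frames
#'
#' Computes the macro (per-frame, then averaged) Dice, IoU, mean pixel
#' accuracy and per-chamber pixel accuracy of a sequence of predicted label
#' maps against references.  Per-frame Dice/IoU are themselves macro
#' averages over the four chamber classes (empty-empty pairs score 1).
#'
#' @param preds,gts lists of integer label maps, aligned.
#' @return object of class `metrics_report`: list with `dice`, `iou`,
#'   `mean_pixel_accuracy`, `per_class` (data frame over classes 1-4) and
#'   `n_items`.
#' @export
metrics_report <- function(preds, gts) {
  if (length(preds) != length(gts)) stop("preds and gts must be aligned")
  if (length(preds) == 0) stop("empty evaluation set")
  per_frame <- function(p, g) {
    d <- vapply(1:4, function(k) dice(p == k, g == k), numeric(1))
    j <- vapply(1:4, function(k) iou(p == k, g == k), numeric(1))
    pa <- vapply(1:4, function(k) pixel_accuracy(p, g, k), numeric(1))
    c(dice = mean(d), iou = mean(j), mpa = mean_pixel_accuracy(p, g),
      d, j, pa)
  }
  m <- vapply(seq_along(preds), function(i) per_frame(preds[[i]], gts[[i]]),
              numeric(15))
  avg <- rowMeans(m)
  structure(list(
    dice = avg[["dice"]],
    iou = avg[["iou"]],
    mean_pixel_accuracy = avg[["mpa"]],
    per_class = data.frame(class = 1:4,
                           chamber = c("left ventricle", "left atrium",
                                       "right ventricle", "right atrium"),
                           dice = avg[4:7], iou = avg[8:11],
                           pixel_accuracy = avg[12:15]),
    n_items = length(preds)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d frames (macro averages)\n",
              x$n_items))
  cat(sprintf("  Dice %.4f | IoU %.4f | mean pixel accuracy %.4f\n",
              x$dice, x$iou, x$mean_pixel_accuracy))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Before/after-correction Dice comparison
#'
#' Per-chamber macro Dice of the original predictions and of the corrected
#' predictions against ground truth, over the full set and over a flagged
#' subset of frame indices (e.g. those a reviewer marked as needing
#' correction), with differences (corrected minus original).
#'
#' @param preds,corrected,gts aligned lists of label maps.
#' @param flagged_subset integer indices into the sequences.
#' @return data frame, one row per chamber.
#' @export
compare_correction <- function(preds, corrected, gts,
                               flagged_subset = integer(0)) {
  n <- length(gts)
  if (length(preds) != n || length(corrected) != n)
    stop("preds, corrected and gts must be aligned")
  if (length(flagged_subset) &&
      (min(flagged_subset) < 1 || max(flagged_subset) > n))
    stop("flagged_subset out of range")
  mean_dice <- function(maps, idx, k)
    mean(vapply(idx, function(i) dice(maps[[i]] == k, gts[[i]] == k),
                numeric(1)))
  rows <- lapply(1:4, function(k) {
    all_idx <- seq_len(n)
    orig <- mean_dice(preds, all_idx, k)
    corr <- mean_dice(corrected, all_idx, k)
    of <- if (length(flagged_subset)) mean_dice(preds, flagged_subset, k)
          else NA_real_
    cf <- if (length(flagged_subset)) mean_dice(corrected, flagged_subset, k)
          else NA_real_
    data.frame(class = k,
               chamber = c("left ventricle", "left atrium",
                           "right ventricle", "right atrium")[k],
               dice_original = orig, dice_corrected = corr,
               difference = corr - orig,
               dice_original_flagged = of, dice_corrected_flagged = cf,
               difference_flagged = cf - of)
  })
  do.call(rbind, rows)
}
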