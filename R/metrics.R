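#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,truth Binary masks (logical or 0/1 numeric) of equal shape.
#' @return A named list of class `"confusion_counts"` with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("prediction and reference masks have different shapes")
  p <- as.logical(pred); y <- as.logical(truth)
  structure(list(TP = sum(p & y), FP = sum(p & !y),
                 TN = sum(!p & !y), FN = sum(!p & y)),
            class = "confusion_counts")
}

#' Add two confusion-count accumulators
#' @param e1,e2 `confusion_counts` objects.
#' @return Their element-wise sum.
#' @export
"+.confusion_counts" <- function(e1, e2) {
  structure(list(TP = e1$TP + e2$TP, FP = e1$FP + e2$FP,
                 TN = e1$TN + e2$TN, FN = e1$FN + e2$FN),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Computes `Dice = 2 TP / (2 TP + FN + FP)`,
#' `IoU = TP / (TP + FN + FP)`, `Sensitivity = TP / (TP + FN)` and
#' `Specificity = TN / (TN + FP)`. When both the reference and the
#' prediction are empty (`TP + FN = 0` and `FP = 0`), Dice, IoU and
#' sensitivity are defined as 1; if exactly one is empty they are 0.
#' An all-positive reference (`TN + FP = 0`) gives specificity 1.
#'
#' @param counts A [confusion_counts()] object (or a list with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return Named numeric vector `c(dice, iou, sensitivity, specificity)`,
#'   each in `[0, 1]`.
#' @export
#' @examples
#' segmentation_metrics(confusion_counts(c(1,1,1,0), c(1,1,0,0)))
segmentation_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  denom_pos <- 2 * TP + FN + FP
  if (denom_pos == 0) {
    dice <- 1; iou <- 1; sens <- 1
  } else {
    dice <- 2 * TP / denom_pos
    iou <- TP / (TP + FN + FP)
    sens <- if (TP + FN == 0) 0 else TP / (TP + FN)
  }
  spec <- if (TN + FP == 0) 1 else TN / (TN + FP)
  c(dice = dice, iou = iou, sensitivity = sens, specificity = spec)
}

#' Binary cross-entropy on capsule lengths
#'
#' Mean over pixels of `-[y log p + (1 - y) log(1 - p)]`, where `p` is the
#' segmentation capsule length. Lengths are clamped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param lengths Predicted foreground probabilities in `[0, 1)`.
#' @param mask Binary reference mask of the same shape.
#' @param eps Clamp margin (default `1e-7`).
#' @return Scalar loss.
#' @export
#' @examples
#' bce_loss(c(0.9, 0.2), c(1, 0))   # -(log 0.9 + log 0.8) / 2
bce_loss <- function(lengths, mask, eps = 1e-7) {
  if (length(lengths) != length(mask))
    stop("lengths and mask have different sizes")
  p <- pmin(pmax(as.numeric(lengths), eps), 1 - eps)
  y <- as.numeric(mask)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# gradient of bce_loss wrt lengths (same clamping)
.bce_grad <- function(lengths, mask, eps = 1e-7) {
  p <- pmin(pmax(as.numeric(lengths), eps), 1 - eps)
  y <- as.numeric(mask)
  g <- (p - y) / (p * (1 - p)) / length(p)
  array(g, dim(lengths) %||% length(lengths))
}
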