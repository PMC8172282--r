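#' Confusion counts over an evaluation region
#'
#' Pixel tallies of a predicted vessel mask against a reference mask,
#' restricted to `region` (conventionally the field of view, so the
#' uninformative dark surround does not inflate specificity). TP and FP are
#' vessel and background pixels predicted as vessel; FN and TN are vessel and
#' background pixels predicted as background.
#'
#' @param pred,truth Logical matrices of identical shape (TRUE = vessel).
#' @param region Optional logical matrix; `NULL` evaluates every pixel.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(pred, truth, region = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ", call. = FALSE)
  if (!is.null(region) && !identical(dim(region), dim(pred)))
    stop("region shape differs from masks", call. = FALSE)
  sel <- if (is.null(region)) TRUE else as.logical(region)
  p <- as.logical(pred)[sel]
  t <- as.logical(truth)[sel]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity
#'
#' Standard segmentation scores from confusion counts:
#' `Acc = (TP + TN) / (TP + FP + TN + FN)`, `Se = TP / (TP + FN)`,
#' `Sp = TN / (TN + FP)`.
#'
#' @param counts A [confusion()] result, or any list with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @return List of class `seg_metrics` with `acc`, `se`, `sp`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop("negative counts", call. = FALSE)
  if (tp + fn == 0)
    stop("sensitivity undefined: TP + FN is zero (no vessel pixels in truth)",
         call. = FALSE)
  if (tn + fp == 0)
    stop("specificity undefined: TN + FP is zero (no background pixels in truth)",
         call. = FALSE)
  structure(list(acc = (tp + tn) / (tp + fp + tn + fn),
                 se = tp / (tp + fn),
                 sp = tn / (tn + fp)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("Acc %.4f  Se %.4f  Sp %.4f\n", x$acc, x$se, x$sp))
  invisible(x)
}

#' Dice overlap between two masks
#'
#' `2|A and B| / (|A| + |B|)` over `region`; 1 when both masks are empty.
#'
#' @inheritParams confusion
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, truth, region = NULL) {
  cc <- confusion(pred, truth, region)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) 1 else 2 * cc$tp / denom
}
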