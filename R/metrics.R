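#' Pixel confusion counts for disease-spot detection
#'
#' Compares a predicted binary mask with the expected one, with 1 meaning
#' disease spot. Counts satisfy `K_TP + K_FP + K_TN + K_FN = h * w`.
#'
#' @param pred,truth Binary matrices of identical dimensions.
#' @return Named numeric vector `c(K_TP, K_FP, K_TN, K_FN)`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- normalize_label(pred)
  truth <- normalize_label(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth dimensions differ", call. = FALSE)
  }
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  c(K_TP = tp, K_FP = fp, K_TN = tn, K_FN = fn)
}

# ratio with the 0/0 -> 1 convention (an absent class predicted absent is a
# perfect prediction of that class)
safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' Segmentation metrics from confusion counts
#'
#' The five pixel-level performance indexes: pixel accuracy
#' `PA = (TP+TN)/total`; mean pixel accuracy
#' `MPA = (TP/(TP+FP) + TN/(TN+FN))/2`; class pixel accuracy
#' `CPA = TP/(TP+FP)`; intersection-over-union `IoU = TP/(TP+FN+FP)`; and
#' mean IoU `MIoU = (TP/(TP+FN+FP) + TN/(TN+FP+FN))/2`. Any 0/0 term is
#' defined as 1 so the metrics stay meaningful on spot-free images.
#'
#' @param counts Output of [confusion_counts()] (named vector with `K_TP`,
#'   `K_FP`, `K_TN`, `K_FN`).
#' @return A one-row tibble with columns `PA`, `MPA`, `CPA`, `IoU`, `MIoU`,
#'   each in `[0, 1]`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["K_TP"]]; fp <- counts[["K_FP"]]
  tn <- counts[["K_TN"]]; fn <- counts[["K_FN"]]
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative counts", call. = FALSE)
  total <- tp + fp + tn + fn
  if (total <= 0) stop("total pixel count must be positive", call. = FALSE)
  tibble::tibble(
    PA = (tp + tn) / total,
    MPA = (safe_ratio(tp, tp + fp) + safe_ratio(tn, tn + fn)) / 2,
    CPA = safe_ratio(tp, tp + fp),
    IoU = safe_ratio(tp, tp + fn + fp),
    MIoU = (safe_ratio(tp, tp + fn + fp) + safe_ratio(tn, tn + fp + fn)) / 2
  )
}

#' Per-image intersection over union
#'
#' `|pred & truth| / |pred | truth|`; defined as 1 when both masks are empty.
#'
#' @param pred,truth Binary matrices of identical dimensions.
#' @return A number in `[0, 1]`.
#' @export
image_iou <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  safe_ratio(cc[["K_TP"]], cc[["K_TP"]] + cc[["K_FP"]] + cc[["K_FN"]])
}

#' Dice-style score over a test set
#'
#' Twice the mean of the per-image IoU values (the framework's `d_t`); with
#' the default factor 2 the score lies in `[0, 2]`. The factor only rescales
#' rewards uniformly, since the reward uses differences of `d_t`.
#'
#' @param per_image_ious Numeric vector of per-image IoU values in `[0, 1]`.
#' @param dice_factor Leading constant (default 2).
#' @return A list of class `dice_score` with elements `d` and `n_test`.
#' @export
dice_ratio <- function(per_image_ious, dice_factor = 2) {
  if (length(per_image_ious) == 0L) {
    stop("need at least one per-image IoU", call. = FALSE)
  }
  stopifnot(all(per_image_ious >= 0), all(per_image_ious <= 1))
  structure(list(d = dice_factor * mean(per_image_ious),
                 n_test = length(per_image_ious)),
            class = "dice_score")
}

#' Step reward
#'
#' `100 * (d_t - d_prev)`: one hundred times the change in the Dice-style
#' score caused by fine-tuning on the augmented set.
#'
#' @param d_t,d_prev Dice-style scores (numbers, or [dice_ratio()] results).
#' @return A number.
#' @export
reward <- function(d_t, d_prev) {
  if (inherits(d_t, "dice_score")) d_t <- d_t$d
  if (inherits(d_prev, "dice_score")) d_prev <- d_prev$d
  stopifnot(is.finite(d_t), is.finite(d_prev))
  100 * (d_t - d_prev)
}
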