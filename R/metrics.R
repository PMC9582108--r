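#' Pixel confusion counts between two binary masks
#'
#' Compares a predicted and a ground-truth mask pixel by pixel and returns the
#' four confusion counts that all overlap metrics are computed from: true
#' positives (both 1), false positives (prediction 1, truth 0), false
#' negatives (prediction 0, truth 1) and true negatives (both 0).
#'
#' @param pred,gt binary masks (matrices or arrays of 0/1) of identical shape.
#' @return A `"confusion_counts"` object with fields `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("mask shapes differ: pred is ", paste(dim(pred), collapse = "x"),
         ", gt is ", paste(dim(gt), collapse = "x"))
  p <- as.numeric(pred); g <- as.numeric(gt)
  if (!all(p %in% c(0, 1)))
    stop("pred is not binary: values outside {0, 1}")
  if (!all(g %in% c(0, 1)))
    stop("gt is not binary: values outside {0, 1}")
  structure(list(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
                 tn = sum(p == 0 & g == 0), fn = sum(p == 0 & g == 1)),
            class = "confusion_counts")
}

as_counts <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  c
}

#' Segmentation metrics from confusion counts
#'
#' Scalar overlap metrics on hard masks:
#' \describe{
#'   \item{`pixel_accuracy`}{`(TP + TN) / (TP + FP + TN + FN)`, the fraction of
#'     correctly labelled pixels.}
#'   \item{`dice`}{`2 TP / (2 TP + FP + FN)`, the Dice similarity coefficient.}
#'   \item{`jaccard`}{`TP / (TP + FP + FN)`, the Jaccard similarity index
#'     (intersection over union).}
#'   \item{`tversky`}{`TP / (TP + alpha FN + beta FP)`, the Tversky index;
#'     `alpha = beta = 0.5` recovers Dice and `alpha = beta = 1` recovers
#'     Jaccard.}
#' }
#' When both masks are empty (`TP = FP = FN = 0`) the overlap ratios are
#' formally 0/0; by convention two empty masks agree perfectly and
#' `empty_value = 1` is returned (configurable).
#'
#' @param c a [confusion_counts()] object.
#' @param empty_value value returned when the denominator is zero.
#' @param alpha,beta nonnegative Tversky weights on FN and FP.
#' @return A number in `[0, 1]`.
#' @export
pixel_accuracy <- function(c) {
  c <- as_counts(c)
  tot <- c$tp + c$fp + c$tn + c$fn
  if (tot == 0) stop("accuracy undefined: no pixels compared")
  (c$tp + c$tn) / tot
}

#' @rdname pixel_accuracy
#' @export
dice <- function(c, empty_value = 1) {
  c <- as_counts(c)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(empty_value)
  2 * c$tp / den
}

#' @rdname pixel_accuracy
#' @export
jaccard <- function(c, empty_value = 1) {
  c <- as_counts(c)
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(empty_value)
  c$tp / den
}

#' @rdname pixel_accuracy
#' @export
tversky <- function(c, alpha, beta, empty_value = 1) {
  c <- as_counts(c)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative")
  den <- c$tp + alpha * c$fn + beta * c$fp
  if (den == 0) return(empty_value)
  c$tp / den
}

#' Threshold Jaccard index
#'
#' Zeroes out Jaccard scores below a cutoff: segmentations with `JSI <
#' threshold` are considered unusable and scored 0, all others keep their JSI.
#' The cutoff 0.65 follows the ISIC 2018 challenge rule; the zero branch uses a
#' strict `<`, so a score exactly at the threshold is kept.
#'
#' @param jsi Jaccard index value(s) in `[0, 1]` (vectorized).
#' @param threshold cutoff, default 0.65.
#' @return `0` where `jsi < threshold`, otherwise `jsi`.
#' @examples
#' threshold_jaccard(c(0.5, 0.65, 0.7))  # 0.00 0.65 0.70
#' @export
threshold_jaccard <- function(jsi, threshold = 0.65) {
  if (any(jsi < 0 | jsi > 1, na.rm = TRUE) || any(is.na(jsi)))
    stop("jsi must lie in [0, 1]")
  ifelse(jsi < threshold, 0, jsi)
}

#' Tversky loss hyperparameters
#'
#' Bundle of the soft-Tversky/Focal-Tversky hyperparameters: `alpha` weights
#' false negatives, `beta` weights false positives, `gamma > 0` is the focal
#' exponent, and `epsilon` smooths the soft ratio against 0/0. Defaults
#' `alpha = 0.7`, `beta = 0.3`, `gamma = 4/3` follow the Focal Tversky loss
#' literature (penalize missed lesion pixels more, mildly focus training on
#' poorly segmented images). `alpha + beta = 1` is not enforced: the Jaccard
#' corner of the Tversky family needs `alpha = beta = 1`.
#'
#' @param alpha,beta nonnegative weights on FN and FP.
#' @param gamma positive focal exponent.
#' @param epsilon small positive smoothing constant.
#' @return A `"tversky_params"` object.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.3, gamma = 4 / 3,
                           epsilon = 1e-6) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative")
  if (gamma <= 0) stop("gamma must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon),
            class = "tversky_params")
}

#' Focal Tversky loss
#'
#' Differentiable training loss `FTL = (1 - TI)^gamma` on a map of foreground
#' probabilities, where `TI` is the soft Tversky index computed from soft
#' counts `TP = sum(p g)`, `FN = sum((1 - p) g)`, `FP = sum(p (1 - g))`,
#' smoothed by `epsilon` in numerator and denominator. A perfect hard
#' prediction gives a loss of 0 (up to `epsilon`); `gamma > 1` amplifies the
#' loss gradient on images with a poor Tversky index.
#'
#' @param pred_probs per-pixel foreground probabilities in `[0, 1]`, same shape
#'   as `gt`.
#' @param gt binary ground-truth mask.
#' @param params a [tversky_params()].
#' @return Nonnegative scalar loss.
#' @examples
#' g <- matrix(c(1, 0, 1, 0), 2)
#' focal_tversky_loss(g, g, tversky_params())  # ~0
#' @export
focal_tversky_loss <- function(pred_probs, gt, params = tversky_params()) {
  stopifnot(inherits(params, "tversky_params"))
  p <- as.numeric(pred_probs)
  if (!identical(dim(pred_probs), dim(gt)) &&
      length(pred_probs) != length(gt))
    stop("shape mismatch between pred_probs and gt")
  if (any(p < 0 | p > 1))
    stop("pred_probs must lie in [0, 1]")
  g <- as.numeric(gt)
  if (!all(g %in% c(0, 1))) stop("gt is not binary")
  op_ftl(pred_probs, gt, params$alpha, params$beta, params$gamma,
         params$epsilon)
}

#' Soft Tversky index
#'
#' The smoothed Tversky index on probabilities that [focal_tversky_loss()]
#' raises to the focal exponent.
#'
#' @inheritParams focal_tversky_loss
#' @return Scalar in `(0, 1]`.
#' @export
soft_tversky_index <- function(pred_probs, gt, params = tversky_params()) {
  p <- as.numeric(pred_probs); g <- as.numeric(gt)
  tp <- sum(p * g); fn <- sum((1 - p) * g); fp <- sum(p * (1 - g))
  (tp + params$epsilon) /
    (tp + params$alpha * fn + params$beta * fp + params$epsilon)
}
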