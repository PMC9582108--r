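#' Evaluate predicted masks against ground truth
#'
#' Computes per-image Dice, Jaccard, Threshold Jaccard and pixel accuracy at
#' the ground-truth resolution (predictions are resized to it with nearest
#' neighbour if needed), plus macro-averaged aggregates: metrics are computed
#' per image and then averaged, overall and per lesion class. Images whose
#' Jaccard index falls below the threshold (0.65) form the failure list —
#' segmentations considered unusable.
#'
#' @param pred_masks named list of binary prediction masks.
#' @param gt_masks named list of binary ground-truth masks; names must match
#'   `pred_masks` exactly.
#' @param labels optional named class vector (see [read_class_labels()]).
#' @param threshold Threshold Jaccard cutoff, default 0.65.
#' @return A `"metric_report"`: list with `per_image` (data.frame id, class,
#'   dice, jsi, threshold_jaccard, accuracy), `overall` (mean of each metric),
#'   `per_class` (data.frame of per-class means and n, when labels given) and
#'   `failures` (ids with jsi < threshold).
#' @export
evaluate_dataset <- function(pred_masks, gt_masks, labels = NULL,
                             threshold = 0.65) {
  ids_p <- names(pred_masks); ids_g <- names(gt_masks)
  if (is.null(ids_p) || is.null(ids_g))
    stop("pred_masks and gt_masks must be named by image id")
  if (!setequal(ids_p, ids_g)) {
    stop("prediction/ground-truth ids differ; only in predictions: ",
         paste(setdiff(ids_p, ids_g), collapse = ", "),
         "; only in ground truth: ",
         paste(setdiff(ids_g, ids_p), collapse = ", "))
  }
  rows <- lapply(ids_g, function(id) {
    gt <- gt_masks[[id]]
    pr <- pred_masks[[id]]
    if (!identical(dim(pr), dim(gt))) pr <- resize_mask(pr, dim(gt))
    cc <- confusion_counts(pr, gt)
    j <- jaccard(cc)
    data.frame(id = id,
               class = if (!is.null(labels) && id %in% names(labels))
                 labels[[id]] else NA_character_,
               dice = dice(cc), jsi = j,
               threshold_jaccard = threshold_jaccard(j, threshold),
               accuracy = pixel_accuracy(cc),
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  metrics <- c("dice", "jsi", "threshold_jaccard", "accuracy")
  overall <- colMeans(per_image[metrics])
  per_class <- NULL
  if (!is.null(labels)) {
    per_class <- per_class_report(
      structure(list(per_image = per_image), class = "metric_report"), labels)
  }
  structure(list(per_image = per_image, overall = overall,
                 per_class = per_class,
                 failures = per_image$id[per_image$jsi < threshold],
                 threshold = threshold),
            class = "metric_report")
}

#' Per-lesion-class metric table
#'
#' Aggregates a report's per-image metrics by lesion class (macro average
#' within each class), with the per-class sample count. Classes absent from
#' the data do not appear; every image must be labelled.
#'
#' @param report a `"metric_report"` from [evaluate_dataset()].
#' @param labels named class vector covering every image id in the report.
#' @return data.frame with columns class, n, dice, jsi, threshold_jaccard,
#'   accuracy.
#' @export
per_class_report <- function(report, labels) {
  pi <- report$per_image
  missing <- setdiff(pi$id, names(labels))
  if (length(missing))
    stop("unlabelled image ids: ", paste(missing, collapse = ", "))
  pi$class <- unname(labels[pi$id])
  metrics <- c("dice", "jsi", "threshold_jaccard", "accuracy")
  agg <- lapply(split(pi, pi$class), function(d) {
    cbind(data.frame(class = d$class[1], n = nrow(d)),
          as.data.frame(as.list(colMeans(d[metrics]))))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$class), ]
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", nrow(x$per_image), " images\n", sep = "")
  cat(sprintf("  mean dice %.4f | jaccard %.4f | threshold jaccard %.4f | accuracy %.4f\n",
              x$overall["dice"], x$overall["jsi"],
              x$overall["threshold_jaccard"], x$overall["accuracy"]))
  cat("  failures (JSI < ", x$threshold, "): ", length(x$failures), "\n",
      sep = "")
  if (!is.null(x$per_class)) {
    cat("  per-class means:\n")
    print(x$per_class, row.names = FALSE)
  }
  invisible(x)
}

#' Prediction/ground-truth comparison overlay
#'
#' Renders the pixelwise confusion of a mask pair as an RGB image: true
#' positives green, false positives red, false negatives blue, true negatives
#' black. The color histogram of the overlay is exactly the confusion counts.
#'
#' @param pred,gt binary masks of identical shape.
#' @return `H x W x 3` RGB array.
#' @export
comparison_image <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("mask shapes differ: pred is ", paste(dim(pred), collapse = "x"),
         ", gt is ", paste(dim(gt), collapse = "x"))
  p <- as.matrix(pred); g <- as.matrix(gt)
  img <- array(0, c(dim(p), 3L))
  img[, , 1][p == 1 & g == 0] <- 1  # FP red
  img[, , 2][p == 1 & g == 1] <- 1  # TP green
  img[, , 3][p == 0 & g == 1] <- 1  # FN blue
  img
}

#' Write a metric report to CSV
#'
#' @param report a `"metric_report"`.
#' @param path output CSV path for the per-image table; aggregate rows are
#'   appended with id `"__overall__"` (and `"__class_<CLS>__"` when per-class
#'   results exist).
#' @export
write_report <- function(report, path) {
  pi <- report$per_image
  ov <- data.frame(id = "__overall__", class = NA_character_,
                   dice = report$overall[["dice"]],
                   jsi = report$overall[["jsi"]],
                   threshold_jaccard = report$overall[["threshold_jaccard"]],
                   accuracy = report$overall[["accuracy"]])
  out <- rbind(pi, ov)
  if (!is.null(report$per_class)) {
    pc <- report$per_class
    out <- rbind(out,
                 data.frame(id = paste0("__class_", pc$class, "__"),
                            class = pc$class, dice = pc$dice, jsi = pc$jsi,
                            threshold_jaccard = pc$threshold_jaccard,
                            accuracy = pc$accuracy))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
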