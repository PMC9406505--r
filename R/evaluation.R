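# Clinical evaluation layer: millimetre object/distance errors, suitability
# classification of the ETT-Carina distance, detection counting at the 10 mm
# true-positive threshold, error distributions, and 5-fold aggregation.

#' Euclidean object error in millimetres
#' @param pred,gt points `c(x, y)` in pixels
#' @param spacing pixel spacing in mm/px
#' @return error in mm (NA if pred has missing coordinates)
#' @export
object_error <- function(pred, gt, spacing) {
  if (any(is.na(pred))) return(NA_real_)
  sqrt(sum((pred - gt)^2)) * spacing
}

#' ETT-Carina distance error in millimetres
#'
#' Absolute difference between the ground-truth and predicted tip-Carina
#' distances (each a Euclidean length converted by the pixel spacing).
#' @param pred_tip,pred_carina,gt_tip,gt_carina points in pixels
#' @param spacing pixel spacing in mm/px
#' @return error in mm (NA if any predicted point is missing)
#' @export
distance_error <- function(pred_tip, pred_carina, gt_tip, gt_carina, spacing) {
  if (any(is.na(pred_tip)) || any(is.na(pred_carina))) return(NA_real_)
  dg <- sqrt(sum((gt_tip - gt_carina)^2))
  dp <- sqrt(sum((pred_tip - pred_carina)^2))
  abs(dg - dp) * spacing
}

#' Suitability of an ETT-Carina distance
#'
#' The tube position is suitable iff the distance lies in the closed
#' interval \[20, 70\] mm.
#' @param distance_mm ETT-Carina distance in mm (vectorized)
#' @return "suitable" / "unsuitable" (NA distances give "undetected")
#' @export
classify_suitability <- function(distance_mm) {
  ifelse(is.na(distance_mm), "undetected",
         ifelse(distance_mm >= 20 & distance_mm <= 70,
                "suitable", "unsuitable"))
}

#' Keypoint detection counts and recall/precision
#'
#' A predicted point with object error <= `tp_threshold` is a true positive;
#' a predicted point farther away counts as a false positive *and* its
#' missed ground truth as a false negative; an absent prediction is a false
#' negative. Recall = TP/(TP+FN), precision = TP/(TP+FP).
#'
#' @param errors_mm per-image object errors (NA = no prediction)
#' @param tp_threshold true-positive radius in mm (default 10)
#' @return list with counts `TP`, `FP`, `FN` and `recall`, `precision`
#' @export
detection_counts <- function(errors_mm, tp_threshold = 10) {
  predicted <- !is.na(errors_mm)
  tp <- sum(predicted & errors_mm <= tp_threshold)
  fp <- sum(predicted & errors_mm > tp_threshold)
  fn <- sum(!predicted) + fp  # a wrong region also misses its GT
  list(TP = tp, FP = fp, FN = fn,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Accuracy of a suitability confusion matrix
#'
#' Rows are predictions (suitable, unsuitable, undetected), columns ground
#' truth (suitable, unsuitable); accuracy is the correctly classified
#' fraction of all images, with undetected rows always incorrect.
#' @param m 3 x 2 count matrix
#' @return accuracy in percent
#' @export
confusion_accuracy <- function(m) {
  stopifnot(nrow(m) == 3L, ncol(m) == 2L)
  unname(100 * (m[1, 1] + m[2, 2]) / sum(m))
}

#' Build the diagnosis confusion matrix from labels
#' @param predicted character vector in
#'   \{"suitable", "unsuitable", "undetected"\}
#' @param truth character vector in \{"suitable", "unsuitable"\}
#' @return 3 x 2 count matrix
#' @export
confusion_matrix <- function(predicted, truth) {
  pr <- factor(predicted, levels = c("suitable", "unsuitable", "undetected"))
  gt <- factor(truth, levels = c("suitable", "unsuitable"))
  unclass(table(pr, gt))
}

#' Unweighted mean of per-fold values
#' @param values numeric per-fold vector
#' @return arithmetic mean
#' @export
aggregate_folds <- function(values) mean(values)

#' Relative change of a value against a reference, in percent
#' @param ours,reference numeric scalars
#' @return `(ours - reference) / reference * 100`, rounded to 2 decimals
#' @export
relative_change <- function(ours, reference) {
  round((ours - reference) / reference * 100, 2)
}

#' Cumulative error distribution at fixed thresholds
#'
#' Fraction of images with error <= t, in percent. Undetected images (NA
#' errors) stay in the denominator but never reach the numerator.
#' @param errors_mm per-image errors (NA = undetected)
#' @param thresholds mm thresholds (default 5/10/15/20)
#' @return named numeric vector of percentages (non-decreasing)
#' @export
error_distribution <- function(errors_mm, thresholds = c(5, 10, 15, 20)) {
  if (length(errors_mm) == 0L) stop("error_distribution: empty error list")
  n <- length(errors_mm)
  out <- vapply(thresholds, function(t)
    100 * sum(!is.na(errors_mm) & errors_mm <= t) / n, numeric(1))
  names(out) <- paste0("le_", thresholds, "mm")
  out
}

# population standard deviation (n divisor)
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Per-image evaluation of predicted keypoints against ground truth
#'
#' @param results list of per-image lists: `keypoints` (a `keypoint_result`),
#'   `gt_tip`, `gt_carina` (pixels), `spacing` (mm/px)
#' @return data.frame with per-image tip/carina object errors, distance
#'   error, predicted and true suitability labels
#' @export
evaluate_images <- function(results) {
  rows <- lapply(results, function(r) {
    kp <- r$keypoints
    tip_err <- object_error(kp$ett_tip$point, r$gt_tip, r$spacing)
    car_err <- object_error(kp$carina$point, r$gt_carina, r$spacing)
    dist_err <- distance_error(kp$ett_tip$point, kp$carina$point,
                               r$gt_tip, r$gt_carina, r$spacing)
    gt_d <- sqrt(sum((r$gt_tip - r$gt_carina)^2)) * r$spacing
    pred_d <- if (any(is.na(kp$ett_tip$point)) || any(is.na(kp$carina$point)))
      NA_real_
    else sqrt(sum((kp$ett_tip$point - kp$carina$point)^2)) * r$spacing
    data.frame(tip_error = tip_err, carina_error = car_err,
               distance_error = dist_err,
               gt_distance = gt_d, pred_distance = pred_d,
               pred_label = classify_suitability(pred_d),
               gt_label = classify_suitability(gt_d),
               tip_provenance = kp$ett_tip$provenance,
               carina_provenance = kp$carina$provenance)
  })
  do.call(rbind, rows)
}

#' Summarize a per-image evaluation table into the clinical report metrics
#'
#' @param per_image data.frame from [evaluate_images()]
#' @param tp_threshold true-positive radius in mm
#' @return list of class `eval_report`: suitability accuracy (%), confusion
#'   matrix, mean/sd errors (mm), recall/precision per keypoint, error
#'   distributions
#' @export
summarize_evaluation <- function(per_image, tp_threshold = 10) {
  cm <- confusion_matrix(per_image$pred_label, per_image$gt_label)
  tip_counts <- detection_counts(per_image$tip_error, tp_threshold)
  car_counts <- detection_counts(per_image$carina_error, tp_threshold)
  structure(list(
    n = nrow(per_image),
    accuracy = confusion_accuracy(cm),
    confusion = cm,
    distance_mean = mean(per_image$distance_error, na.rm = TRUE),
    distance_sd = sd_pop(per_image$distance_error),
    tip_mean = mean(per_image$tip_error, na.rm = TRUE),
    tip_sd = sd_pop(per_image$tip_error),
    carina_mean = mean(per_image$carina_error, na.rm = TRUE),
    carina_sd = sd_pop(per_image$carina_error),
    tip_recall = tip_counts$recall, tip_precision = tip_counts$precision,
    carina_recall = car_counts$recall,
    carina_precision = car_counts$precision,
    distance_distribution = error_distribution(per_image$distance_error),
    tip_distribution = error_distribution(per_image$tip_error),
    carina_distribution = error_distribution(per_image$carina_error)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d images\n", x$n))
  cat(sprintf("  malposition accuracy : %.2f%%\n", x$accuracy))
  cat(sprintf("  distance error       : %.3f +/- %.3f mm\n",
              x$distance_mean, x$distance_sd))
  cat(sprintf("  ETT tip error        : %.3f +/- %.3f mm (recall %.2f%%)\n",
              x$tip_mean, x$tip_sd, 100 * x$tip_recall))
  cat(sprintf("  Carina error         : %.3f +/- %.3f mm (recall %.2f%%)\n",
              x$carina_mean, x$carina_sd, 100 * x$carina_recall))
  invisible(x)
}
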