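# Keypoint post-processing: reduce the raw detections to at most one ETT-tip
# and one Carina point per image. Candidate tip/Carina boxes are re-scored by
# a Gaussian prior centered on the best parent box (ETT / tracheal
# bifurcation) or, absent one, on the image center; a low-confidence winner
# is replaced by a point derived from its parent box.

#' Highest-confidence detection of a class
#'
#' Ties are broken by smaller box area, then by lower row index.
#' @param detections data.frame from [decode_detections()]
#' @param class one of the four class names
#' @return single-row data.frame, or NULL if the class is absent
#' @export
best_box <- function(detections, class) {
  dk <- detections[detections$class == class, , drop = FALSE]
  if (nrow(dk) == 0L) return(NULL)
  area <- (dk$x2 - dk$x1) * (dk$y2 - dk$y1)
  ord <- order(-dk$score, area, seq_len(nrow(dk)))
  dk[ord[1L], , drop = FALSE]
}

#' Gaussian prior weight of a candidate center
#'
#' `exp(-||c - mu||^2 / (2 sigma^2))`: 1 at the prior center, ~0.607 at one
#' sigma, strictly decreasing with distance.
#' @param center candidate box center `c(x, y)`
#' @param prior_center prior mean `c(x, y)`
#' @param sigma prior standard deviation in pixels (> 0)
#' @return weight in (0, 1\]
#' @export
gaussian_weight <- function(center, prior_center, sigma) {
  stopifnot(sigma > 0)
  d2 <- sum((center - prior_center)^2)
  exp(-d2 / (2 * sigma^2))
}

box_center <- function(b) c((b$x1 + b$x2) / 2, (b$y1 + b$y2) / 2)

# pick the best feature-point candidate of `child` under the Gaussian prior
# from `parent`, then refine against the parent box
select_keypoint <- function(detections, child, parent, image_size,
                            conf_thresh, sigma, parent_point) {
  pb <- best_box(detections, parent)
  prior <- if (!is.null(pb)) box_center(pb) else image_size / 2
  cand <- detections[detections$class == child, , drop = FALSE]
  if (nrow(cand) > 0L) {
    w <- vapply(seq_len(nrow(cand)), function(i)
      gaussian_weight(c((cand$x1[i] + cand$x2[i]) / 2,
                        (cand$y1[i] + cand$y2[i]) / 2), prior, sigma),
      numeric(1))
    rescored <- cand$score * w
    best <- cand[which.max(rescored), , drop = FALSE]
    # raw (unweighted) confidence decides whether refinement kicks in
    if (best$score >= conf_thresh || is.null(pb) || best$score >= pb$score) {
      return(list(point = box_center(best), confidence = best$score,
                  provenance = if (child == "ETT_tip") "tip_box_center"
                               else "carina_box_center"))
    }
    # low-confidence child beaten by its parent: derive the point from the
    # parent box instead
    return(parent_point(pb))
  }
  if (!is.null(pb)) return(parent_point(pb))
  list(point = c(NA_real_, NA_real_), confidence = NA_real_,
       provenance = "none")
}

#' Finalize the ETT-tip and Carina keypoints for one image
#'
#' Guarantees at most one tip and one Carina regardless of how many raw
#' candidates exist. A tip whose confidence falls below `conf_thresh` *and*
#' below the best ETT box is replaced by the midpoint of the ETT box's bottom
#' edge; a weak Carina is likewise replaced by the bifurcation box center.
#'
#' @param detections data.frame from [decode_detections()]
#' @param image_size `c(width, height)` in pixels
#' @param conf_thresh refinement trigger on the raw (cls x ctr) confidence
#' @param sigma Gaussian prior standard deviation in pixels; defaults to 1/8
#'   of the image diagonal
#' @return list of class `keypoint_result`: `$ett_tip` and `$carina`, each
#'   with `point` (x, y), `confidence` and `provenance`
#' @export
finalize_keypoints <- function(detections, image_size, conf_thresh = 0.5,
                               sigma = NULL) {
  if (is.null(sigma)) sigma <- sqrt(sum(image_size^2)) / 8
  tip <- select_keypoint(
    detections, "ETT_tip", "ETT", image_size, conf_thresh, sigma,
    parent_point = function(pb) list(
      point = c((pb$x1 + pb$x2) / 2, pb$y2),   # bottom-edge midpoint
      confidence = pb$score, provenance = "ett_box_bottom_mid"))
  car <- select_keypoint(
    detections, "Carina", "tracheal_bifurcation", image_size, conf_thresh,
    sigma,
    parent_point = function(pb) list(
      point = box_center(pb), confidence = pb$score,
      provenance = "bifurcation_box_center"))
  structure(list(ett_tip = tip, carina = car), class = "keypoint_result")
}
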