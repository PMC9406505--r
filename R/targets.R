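# Per-location training targets and detection decoding (anchor-free,
# FCOS-style): every feature-map location is a point in image space that
# regresses its distances (l, t, r, b) to the sides of the box containing it.

#' Centerness of a location from its side distances
#'
#' `sqrt((min(l,r)/max(l,r)) * (min(t,b)/max(t,b)))`: 1 at the box center,
#' falling towards 0 near the sides.
#' @param l,t,r,b distances to the left/top/right/bottom box sides
#' @return centerness in \[0, 1\]
#' @export
centerness_target <- function(l, t, r, b) {
  sqrt((pmin(l, r) / pmax(l, r)) * (pmin(t, b) / pmax(t, b)))
}

# image-space center coordinates of a level's locations (0-based pixels)
level_centers <- function(stride, H, W) {
  off <- floor(stride / 2)
  list(x = off + (seq_len(W) - 1L) * stride,
       y = off + (seq_len(H) - 1L) * stride)
}

#' Assign ground-truth targets to every pyramid location
#'
#' A location is positive for a box iff it lies strictly inside it and the
#' largest of its four side distances falls in the level's range; a location
#' inside several boxes takes the smallest-area one. Background locations get
#' label 0.
#'
#' @param instances an `instance_set` (boxes in input-image pixels)
#' @param geometry list of per-level lists `list(stride, H, W)` for P3..P7
#' @param level_ranges 5 x 2 matrix of (lo, hi\] regression ranges
#' @return list per level: `labels` (H x W integer, 0 = background, else
#'   class index), `reg` (H x W x 4 distances l,t,r,b), `ctr` (H x W)
#' @export
assign_targets <- function(instances, geometry,
                           level_ranges = rbind(c(0, 64), c(64, 128),
                                                c(128, 256), c(256, 512),
                                                c(512, Inf))) {
  boxes <- if (is.null(instances)) list() else instances$boxes
  nb <- length(boxes)
  areas <- if (nb) vapply(boxes, bbox_area, numeric(1)) else numeric(0)
  out <- vector("list", length(geometry))
  for (li in seq_along(geometry)) {
    g <- geometry[[li]]
    H <- g$H; W <- g$W
    ctrs <- level_centers(g$stride, H, W)
    cx <- matrix(ctrs$x, H, W, byrow = TRUE)
    cy <- matrix(ctrs$y, H, W)
    labels <- matrix(0L, H, W)
    reg <- array(0, dim = c(H, W, 4L))
    ctr <- matrix(0, H, W)
    best_area <- matrix(Inf, H, W)
    lo <- level_ranges[li, 1]; hi <- level_ranges[li, 2]
    for (bi in seq_len(nb)) {
      b <- boxes[[bi]]
      l <- cx - b[1]; t <- cy - b[2]; r <- b[3] - cx; bt <- b[4] - cy
      mx <- pmax(pmax(l, r), pmax(t, bt))
      pos <- (l > 0) & (t > 0) & (r > 0) & (bt > 0) & (mx > lo) & (mx <= hi) &
        (areas[bi] < best_area)
      if (!any(pos)) next
      labels[pos] <- bi
      best_area[pos] <- areas[bi]
      idx <- which(pos)
      reg[cbind(row(labels)[idx], col(labels)[idx], 1L)] <- l[idx]
      reg[cbind(row(labels)[idx], col(labels)[idx], 2L)] <- t[idx]
      reg[cbind(row(labels)[idx], col(labels)[idx], 3L)] <- r[idx]
      reg[cbind(row(labels)[idx], col(labels)[idx], 4L)] <- bt[idx]
      ctr[idx] <- centerness_target(l[idx], t[idx], r[idx], bt[idx])
    }
    out[[li]] <- list(labels = labels, reg = reg, ctr = ctr,
                      stride = g$stride, cx = cx, cy = cy)
  }
  names(out) <- names(geometry)
  out
}

# intersection-over-union of two xyxy boxes
box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  un <- bbox_area(a) + bbox_area(b) - inter
  if (un <= 0) 0 else inter / un
}

#' Greedy non-maximum suppression
#' @param boxes n x 4 matrix (xyxy)
#' @param scores numeric n
#' @param iou_thresh suppression overlap threshold
#' @return indices of kept boxes (decreasing score order)
#' @export
nms <- function(boxes, scores, iou_thresh = 0.6) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1L]
    ious <- vapply(rest, function(j) box_iou(boxes[i, ], boxes[j, ]), numeric(1))
    ord <- rest[ious <= iou_thresh]
  }
  keep
}

#' Decode raw head outputs into scored detections
#'
#' Boxes are `(cx - l, cy - t, cx + r, cy + b)` per location; the final score
#' is the classification score multiplied by the centerness score; low-score
#' locations are dropped and per-class NMS removes duplicates.
#'
#' @param outputs list per level: `cls` (H,W,K logits), `reg` (H,W,4 positive
#'   distances in pixels), `ctr` (H,W,1 logits), `stride`
#' @param image_size `c(width, height)` for box clipping
#' @param score_thresh minimum final (cls x ctr) score
#' @param nms_iou per-class NMS IoU threshold
#' @param max_det cap on detections per image
#' @return data.frame: class, x1, y1, x2, y2, score_cls, score_ctr, score
#' @export
decode_detections <- function(outputs, image_size, score_thresh = 0.05,
                              nms_iou = 0.6, max_det = 100L) {
  rows <- list()
  for (lv in outputs) {
    cls <- lv$cls; if (is_ag(cls)) cls <- cls$val
    reg <- lv$reg; if (is_ag(reg)) reg <- reg$val
    ctr <- lv$ctr; if (is_ag(ctr)) ctr <- ctr$val
    d <- dim(cls); H <- d[1]; W <- d[2]; K <- d[3]
    ctrs <- level_centers(lv$stride, H, W)
    cx <- matrix(ctrs$x, H, W, byrow = TRUE)
    cy <- matrix(ctrs$y, H, W)
    pc <- 1 / (1 + exp(-cls))
    pctr <- as.numeric(1 / (1 + exp(-ctr)))
    for (k in seq_len(K)) {
      sc <- as.numeric(pc[, , k]) * pctr
      sel <- which(sc >= score_thresh)
      if (!length(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        class = ETT_CLASSES[k],
        x1 = as.numeric(cx)[sel] - as.numeric(reg[, , 1])[sel],
        y1 = as.numeric(cy)[sel] - as.numeric(reg[, , 2])[sel],
        x2 = as.numeric(cx)[sel] + as.numeric(reg[, , 3])[sel],
        y2 = as.numeric(cy)[sel] + as.numeric(reg[, , 4])[sel],
        score_cls = as.numeric(pc[, , k])[sel],
        score_ctr = pctr[sel],
        score = sc[sel])
    }
  }
  if (!length(rows))
    return(data.frame(class = character(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0),
                      score_cls = numeric(0), score_ctr = numeric(0),
                      score = numeric(0)))
  det <- do.call(rbind, rows)
  det$x1 <- pmax(det$x1, 0); det$y1 <- pmax(det$y1, 0)
  det$x2 <- pmin(det$x2, image_size[1]); det$y2 <- pmin(det$y2, image_size[2])
  det <- det[det$x2 > det$x1 & det$y2 > det$y1, , drop = FALSE]
  kept <- list()
  for (k in unique(det$class)) {
    dk <- det[det$class == k, , drop = FALSE]
    ki <- nms(as.matrix(dk[, c("x1", "y1", "x2", "y2")]), dk$score, nms_iou)
    kept[[k]] <- dk[ki, , drop = FALSE]
  }
  det <- do.call(rbind, kept)
  det <- det[order(det$score, decreasing = TRUE), , drop = FALSE]
  if (nrow(det) > max_det) det <- det[seq_len(max_det), , drop = FALSE]
  rownames(det) <- NULL
  det
}
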