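# Training objective: focal classification loss + generalized-IoU box
# regression + binary cross-entropy centerness + (Dice + cross-entropy)
# segmentation, summed without weights. Numeric forms below are the
# user-facing/reference implementations; the autodiff counterparts used by
# the trainer are composed from engine primitives so their gradients follow
# from the primitive rules.

#' Focal loss
#'
#' `-a_t (1 - p_t)^gamma log(p_t)` summed and divided by the number of
#' positive samples (anchor-free convention), with
#' `p_t = p` for positives and `1 - p` otherwise, and `a_t` the matching
#' weighting factor.
#'
#' @param p predicted probabilities for the positive class, in (0, 1)
#' @param y labels, 1 for positive and 0 for negative
#' @param alpha weighting factor `a` for positives (negatives get `1-alpha`)
#' @param gamma focusing exponent (default 2)
#' @param n_pos normalizer; defaults to `max(1, sum(y == 1))`
#' @return scalar loss
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2, n_pos = NULL) {
  eps <- 1e-6
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  if (is.null(n_pos)) n_pos <- max(1, sum(y == 1))
  sum(-at * (1 - pt)^gamma * log(pt)) / n_pos
}

#' Generalized IoU of two boxes
#'
#' `GIoU = IoU - |C \ (A U B)| / |C|` with `C` the smallest enclosing box;
#' equals IoU for overlapping/nested boxes and falls to -1 for far-apart
#' boxes.
#' @param a,b xyxy boxes
#' @return GIoU in \[-1, 1\]
#' @export
giou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  areaA <- bbox_area(a); areaB <- bbox_area(b)
  un <- areaA + areaB - inter
  iou <- if (un > 0) inter / un else 0
  cw <- max(a[3], b[3]) - min(a[1], b[1])
  ch <- max(a[4], b[4]) - min(a[2], b[2])
  areaC <- cw * ch
  if (areaC <= 0) return(iou)
  iou - (areaC - un) / areaC
}

#' GIoU loss `1 - GIoU`, in \[0, 2\]
#' @inheritParams giou
#' @return scalar loss
#' @export
giou_loss <- function(a, b) 1 - giou(a, b)

#' Binary cross-entropy centerness loss over positive locations
#' @param pred predicted centerness in \[0, 1\]
#' @param target ground-truth centerness in \[0, 1\]
#' @return mean BCE; 0 when there are no positive locations
#' @export
centerness_loss <- function(pred, target) {
  if (length(pred) == 0L) return(0)
  eps <- 1e-6
  pred <- pmin(pmax(pred, eps), 1 - eps)
  mean(-target * log(pred) - (1 - target) * log(1 - pred))
}

#' Segmentation loss: Dice + lambda x cross-entropy
#'
#' Multi-class cross-entropy over pixels plus soft Dice averaged over the
#' foreground classes, `Dice = (2|A n B| + s)/(|A| + |B| + s)` on softmax
#' probabilities with smoothing `s = 1e-5`.
#'
#' @param logits (H, W, K) class logits, class 1 = background
#' @param mask (H, W) integer ground truth in 0..K-1 (0 = background)
#' @param lambda cross-entropy weight (default 1)
#' @return list with `dice`, `ce` and `total`
#' @export
segmentation_loss <- function(logits, mask, lambda = 1) {
  d <- dim(logits); H <- d[1]; W <- d[2]; K <- d[3]
  m <- matrix(logits, nrow = H * W)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  truth <- as.integer(mask) + 1L  # 1-based class column
  eps <- 1e-9
  ce <- mean(-log(pmax(p[cbind(seq_len(H * W), truth)], eps)))
  smooth <- 1e-5
  present <- which(vapply(seq_len(K - 1L), function(k)
    any(truth == k + 1L), logical(1)))
  dices <- vapply(present, function(k) {
    pk <- p[, k + 1L]
    mk <- as.numeric(truth == k + 1L)
    (2 * sum(pk * mk) + smooth) / (sum(pk) + sum(mk) + smooth)
  }, numeric(1))
  # averaged over the foreground classes present in the ground truth
  dice_term <- if (length(present)) 1 - mean(dices) else 0
  list(dice = dice_term, ce = ce, total = dice_term + lambda * ce)
}

# ---- autodiff losses used by the trainer -----------------------------------

# focal loss over concatenated per-level classification logits
ag_focal_loss <- function(cls_nodes, labels_list, n_classes, alpha, gamma,
                          n_pos) {
  zs <- list(); ys <- list()
  for (i in seq_along(cls_nodes)) {
    lab <- labels_list[[i]]
    HW <- length(lab)
    z <- ag_reshape(cls_nodes[[i]], HW * n_classes)
    y <- as.numeric(outer(as.integer(lab), seq_len(n_classes), `==`))
    zs[[i]] <- z; ys[[i]] <- y
  }
  z <- ag_cat_vec(zs)
  y <- unlist(ys)
  p <- ag_sigmoid(z)
  eps <- 1e-6
  # pt = p where y==1, 1-p otherwise
  pt <- ag_add(ag_mul(p, y), ag_mul(ag_sub(1, p), 1 - y))
  pt <- ag_pmin(ag_pmax(pt, eps), 1 - eps)
  at <- alpha * y + (1 - alpha) * (1 - y)
  term <- ag_mul(ag_mul(ag_pow(ag_sub(1, pt), gamma), ag_scale(ag_log(pt), -1)), at)
  ag_scale(ag_sum(term), 1 / max(1, n_pos))
}

# GIoU loss over positive locations, composed per component vector
ag_giou_loss <- function(pred_lrtb, cx, cy, gt_boxes) {
  l <- pred_lrtb$l; t <- pred_lrtb$t; r <- pred_lrtb$r; b <- pred_lrtb$b
  x1p <- ag_sub(ag_const(cx), l); y1p <- ag_sub(ag_const(cy), t)
  x2p <- ag_add(ag_const(cx), r); y2p <- ag_add(ag_const(cy), b)
  x1g <- gt_boxes[, 1]; y1g <- gt_boxes[, 2]
  x2g <- gt_boxes[, 3]; y2g <- gt_boxes[, 4]
  iw <- ag_relu(ag_sub(ag_pmin(x2p, x2g), ag_pmax(x1p, x1g)))
  ih <- ag_relu(ag_sub(ag_pmin(y2p, y2g), ag_pmax(y1p, y1g)))
  inter <- ag_mul(iw, ih)
  areaP <- ag_mul(ag_sub(x2p, x1p), ag_sub(y2p, y1p))
  areaG <- (x2g - x1g) * (y2g - y1g)
  un <- ag_sub(ag_add(areaP, areaG), inter)
  iou <- ag_div(inter, ag_pmax(un, 1e-9))
  cw <- ag_sub(ag_pmax(x2p, x2g), ag_pmin(x1p, x1g))
  chh <- ag_sub(ag_pmax(y2p, y2g), ag_pmin(y1p, y1g))
  areaC <- ag_pmax(ag_mul(cw, chh), 1e-9)
  gi <- ag_sub(iou, ag_div(ag_sub(areaC, un), areaC))
  ag_mean(ag_sub(1, gi))
}

# BCE-with-logits centerness loss over positives
ag_centerness_loss <- function(z, target) {
  # BCE = t*softplus(-z) + (1-t)*softplus(z)
  loss <- ag_add(ag_mul(ag_softplus(ag_scale(z, -1)), target),
                 ag_mul(ag_softplus(z), 1 - target))
  ag_mean(loss)
}

ag_segmentation_loss <- function(seg_logits, mask, lambda = 1) {
  d <- dim(seg_logits$val); H <- d[1]; W <- d[2]; K <- d[3]
  p <- ag_softmax_c(seg_logits)
  pf <- ag_reshape(p, H * W * K)
  truth <- as.integer(mask) + 1L
  idx <- seq_len(H * W) + (truth - 1L) * (H * W)
  ptrue <- ag_pmax(ag_gather(pf, idx), 1e-9)
  ce <- ag_scale(ag_mean(ag_log(ptrue)), -1)
  smooth <- 1e-5
  present <- which(vapply(seq_len(K - 1L), function(k)
    any(truth == k + 1L), logical(1)))
  dice_terms <- list()
  for (k in present) {
    pk <- ag_gather(pf, seq_len(H * W) + k * (H * W))
    mk <- as.numeric(truth == k + 1L)
    num <- ag_add(ag_scale(ag_sum(ag_mul(pk, mk)), 2), smooth)
    den <- ag_add(ag_add(ag_sum(pk), sum(mk)), smooth)
    dice_terms[[length(dice_terms) + 1L]] <- ag_div(num, den)
  }
  dice <- if (length(dice_terms)) {
    dice_sum <- dice_terms[[1]]
    if (length(dice_terms) > 1L)
      for (k in 2:length(dice_terms)) dice_sum <- ag_add(dice_sum, dice_terms[[k]])
    ag_sub(1, ag_scale(dice_sum, 1 / length(dice_terms)))
  } else ag_const(0)
  list(dice = dice, ce = ce,
       total = ag_add(dice, ag_scale(ce, lambda)))
}

#' Compute the four-term training loss for one image
#'
#' @param fwd model forward output (`$levels`, `$seg`)
#' @param targets per-level targets from [assign_targets()]
#' @param seg_mask (H, W) integer segmentation ground truth, or NULL to skip
#'   the segmentation term
#' @param config a [detector_config()] (focal alpha/gamma, seg lambda)
#' @return list: ag nodes `total`, `cls`, `reg`, `ctr`, `seg` and numeric
#'   `breakdown`
#' @noRd
detection_loss <- function(fwd, targets, seg_mask, config) {
  lv <- fwd$levels
  n_classes <- config$n_classes
  labels_list <- lapply(targets, `[[`, "labels")
  n_pos <- sum(vapply(labels_list, function(x) sum(x > 0L), numeric(1)))
  cls_nodes <- lapply(lv, `[[`, "cls")
  l_cls <- ag_focal_loss(cls_nodes, labels_list, n_classes,
                         config$focal_alpha, config$focal_gamma, n_pos)
  # gather positive-location regression/centerness
  preds_l <- list(); preds_t <- list(); preds_r <- list(); preds_b <- list()
  ctr_z <- list(); ctr_t <- list()
  cxs <- numeric(0); cys <- numeric(0); gts <- NULL
  for (i in seq_along(lv)) {
    tg <- targets[[i]]
    pos <- which(tg$labels > 0L)
    if (!length(pos)) next
    HW <- length(tg$labels)
    regf <- ag_reshape(lv[[i]]$reg, HW * 4L)
    preds_l[[length(preds_l) + 1L]] <- ag_gather(regf, pos)
    preds_t[[length(preds_t) + 1L]] <- ag_gather(regf, pos + HW)
    preds_r[[length(preds_r) + 1L]] <- ag_gather(regf, pos + 2L * HW)
    preds_b[[length(preds_b) + 1L]] <- ag_gather(regf, pos + 3L * HW)
    ctrf <- ag_reshape(lv[[i]]$ctr, HW)
    ctr_z[[length(ctr_z) + 1L]] <- ag_gather(ctrf, pos)
    ctr_t[[length(ctr_t) + 1L]] <- tg$ctr[pos]
    cxs <- c(cxs, tg$cx[pos]); cys <- c(cys, tg$cy[pos])
    gt <- cbind(tg$cx[pos] - tg$reg[cbind(row(tg$labels)[pos], col(tg$labels)[pos], 1L)],
                tg$cy[pos] - tg$reg[cbind(row(tg$labels)[pos], col(tg$labels)[pos], 2L)],
                tg$cx[pos] + tg$reg[cbind(row(tg$labels)[pos], col(tg$labels)[pos], 3L)],
                tg$cy[pos] + tg$reg[cbind(row(tg$labels)[pos], col(tg$labels)[pos], 4L)])
    gts <- rbind(gts, gt)
  }
  if (length(preds_l)) {
    l_reg <- ag_giou_loss(list(l = ag_cat_vec(preds_l), t = ag_cat_vec(preds_t),
                               r = ag_cat_vec(preds_r), b = ag_cat_vec(preds_b)),
                          cxs, cys, gts)
    l_ctr <- ag_centerness_loss(ag_cat_vec(ctr_z), unlist(ctr_t))
  } else {
    l_reg <- ag_const(0)
    l_ctr <- ag_const(0)
  }
  if (!is.null(seg_mask) && !is.null(fwd$seg)) {
    segd <- dim(fwd$seg$val)
    if (!identical(dim(seg_mask), segd[1:2]))
      stop("segmentation mask size mismatch")
    l_seg <- ag_segmentation_loss(fwd$seg, seg_mask, config$seg_lambda)$total
  } else {
    l_seg <- ag_const(0)
  }
  total <- ag_add(ag_add(l_cls, l_reg), ag_add(l_ctr, l_seg))
  list(total = total, cls = l_cls, reg = l_reg, ctr = l_ctr, seg = l_seg,
       breakdown = c(cls = l_cls$val, reg = l_reg$val, ctr = l_ctr$val,
                     seg = l_seg$val, total = total$val, n_pos = n_pos))
}
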