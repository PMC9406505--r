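# Training / inference / evaluation orchestration.
#
# All randomness (case order, augmentation, weight init) flows from the
# configured seed. The clinical-scale schedule follows the reference recipe
# (Adam, lr 1e-4, batch 2, 120 epochs, 5 warm-up epochs then cosine decay,
# shorter-side-800 resize); the desk profile trains the width-reduced model
# on small synthetic images for a fixed iteration budget with a
# width-scaled learning rate.

#' Training configuration
#'
#' @param profile "full" mirrors the clinical-scale recipe (Adam lr 1e-4,
#'   batch 2, 120 epochs); "desk" is the CPU-scale profile: no resize, no
#'   augmentation, single-image steps, 200 iterations, lr 1e-3 scaled up for
#'   the narrow backbone
#' @param ... named overrides (lr, batch_size, epochs, warmup_epochs, iters,
#'   resize_shorter, resize_longer, augment, rotate_deg, crop_frac, seed,
#'   log_every)
#' @return list of class `train_config`
#' @export
train_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- list(profile = profile, warmup_epochs = 5L,
               rotate_deg = 10, crop_frac = 0.9, seed = 1L, log_every = 10L)
  if (profile == "full") {
    base <- c(base, list(lr = 1e-4, batch_size = 2L, epochs = 120L,
                         iters = NULL, resize_shorter = 800L,
                         resize_longer = 1333L, augment = TRUE))
  } else {
    base <- c(base, list(lr = 1e-3, batch_size = 1L, epochs = NULL,
                         iters = 200L, resize_shorter = NULL,
                         resize_longer = NULL, augment = FALSE))
  }
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  stopifnot(is.null(base$epochs) || base$warmup_epochs < base$epochs)
  structure(base, class = "train_config")
}

#' Learning rate at a given iteration: linear warm-up then cosine decay
#' @param iter 1-based iteration index
#' @param total_iters schedule length
#' @param warmup_iters warm-up length in iterations
#' @param base_lr peak learning rate
#' @return learning rate
#' @export
lr_schedule <- function(iter, total_iters, warmup_iters, base_lr) {
  if (warmup_iters > 0 && iter <= warmup_iters) return(base_lr * iter / warmup_iters)
  prog <- (iter - warmup_iters) / max(1, total_iters - warmup_iters)
  0.5 * base_lr * (1 + cos(pi * min(prog, 1)))
}

# ---- geometric transforms (image + landmarks move together) ----------------

#' Rotate an image and landmark set about the image center
#' @param img H x W intensity matrix
#' @param pts n x 2 landmark matrix (0-based x, y)
#' @param angle_deg rotation angle, positive = counter-clockwise in image
#'   coordinates
#' @return list `img`, `pts` (nearest-neighbour resampling; out-of-frame
#'   source pixels take the image median)
#' @export
rotate_case <- function(img, pts, angle_deg) {
  H <- nrow(img); W <- ncol(img)
  th <- angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  # inverse map: for each output pixel, sample the source
  xo <- matrix(0:(W - 1), H, W, byrow = TRUE) - cx
  yo <- matrix(0:(H - 1), H, W) - cy
  xs <- round(cs * xo + sn * yo + cx)
  ys <- round(-sn * xo + cs * yo + cy)
  ok <- xs >= 0 & xs < W & ys >= 0 & ys < H
  out <- matrix(stats::median(img), H, W)
  out[ok] <- img[cbind(ys[ok] + 1L, xs[ok] + 1L)]
  # forward map for the landmarks
  px <- pts[, 1] - cx; py <- pts[, 2] - cy
  npts <- cbind(cs * px - sn * py + cx, sn * px + cs * py + cy)
  list(img = out, pts = npts)
}

#' Nearest-neighbour resize with the matching landmark scaling
#' @param img H x W matrix
#' @param pts n x 2 landmarks
#' @param scale isotropic scale factor
#' @return list `img`, `pts`, `scale`
#' @export
resize_case <- function(img, pts, scale) {
  H <- nrow(img); W <- ncol(img)
  nh <- max(1L, round(H * scale)); nw <- max(1L, round(W * scale))
  yi <- pmin(H, pmax(1L, round((seq_len(nh) - 0.5) / scale + 0.5)))
  xi <- pmin(W, pmax(1L, round((seq_len(nw) - 0.5) / scale + 0.5)))
  list(img = img[yi, xi, drop = FALSE], pts = pts * scale, scale = scale)
}

# color jitter + rotation + crop; returns NULL when a crop would cut off a
# landmark (the sample is then used un-augmented)
augment_case <- function(img, pts, cfg) {
  if (isTRUE(cfg$augment)) {
    img <- pmin(pmax(img * runif(1, 0.9, 1.1) + runif(1, -0.05, 0.05), 0), 1)
    rot <- rotate_case(img, pts, runif(1, -cfg$rotate_deg, cfg$rotate_deg))
    img <- rot$img; pts <- rot$pts
    if (!is.null(cfg$crop_frac) && cfg$crop_frac < 1) {
      H <- nrow(img); W <- ncol(img)
      ch <- round(H * cfg$crop_frac); cw <- round(W * cfg$crop_frac)
      y0 <- sample.int(H - ch + 1L, 1L) - 1L
      x0 <- sample.int(W - cw + 1L, 1L) - 1L
      inside <- all(pts[, 1] >= x0 & pts[, 1] < x0 + cw &
                    pts[, 2] >= y0 & pts[, 2] < y0 + ch)
      if (inside) {
        img <- img[(y0 + 1L):(y0 + ch), (x0 + 1L):(x0 + cw), drop = FALSE]
        pts <- cbind(pts[, 1] - x0, pts[, 2] - y0)
      }
    }
  }
  list(img = img, pts = pts)
}

#' Rasterize the ground-truth segmentation mask from the instance polygons
#'
#' Vectorized even-odd test over the pixel grid; classes are filled in the
#' given order (later classes overwrite earlier ones on overlap).
#' @param instances an `instance_set`
#' @param width,height mask size in pixels
#' @param seg_classes polygon classes to rasterize (default ETT +
#'   tracheal bifurcation)
#' @return integer (height x width) matrix, 0 = background, k = k-th class
#' @export
rasterize_mask <- function(instances, width, height,
                           seg_classes = c("ETT", "tracheal_bifurcation")) {
  mask <- matrix(0L, height, width)
  px <- matrix(0:(width - 1), height, width, byrow = TRUE)
  py <- matrix(0:(height - 1), height, width)
  for (k in seq_along(seg_classes)) {
    poly <- instances$polygons[[seg_classes[k]]]
    if (is.null(poly)) next
    n <- nrow(poly)
    xs <- poly[, 1]; ys <- poly[, 2]
    xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
    cross <- matrix(0L, height, width)
    for (i in seq_len(n)) {
      if (ys[i] == ye[i]) next
      hit <- ((ys[i] > py) != (ye[i] > py)) &
        (px < (xe[i] - xs[i]) * (py - ys[i]) / (ye[i] - ys[i]) + xs[i])
      cross <- cross + hit
    }
    mask[cross %% 2L == 1L] <- k
  }
  mask
}

# build one training sample: augmented image, instance targets, seg mask
prepare_sample <- function(case, det_cfg, train_cfg, feature_box_size) {
  pts <- case$landmarks$points
  img <- case$image
  if (!is.null(train_cfg$resize_shorter)) {
    sc <- train_cfg$resize_shorter / min(dim(img))
    sc <- min(sc, train_cfg$resize_longer / max(dim(img)))
    if (abs(sc - 1) > 1e-9) {
      rs <- resize_case(img, pts, sc)
      img <- rs$img; pts <- rs$pts
      feature_box_size <- feature_box_size * sc
    }
  }
  aug <- augment_case(img, pts, train_cfg)
  img <- aug$img
  pts <- aug$pts
  s <- dim(img)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), s[2] - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), s[1] - 1)
  lm <- landmarks13(pts, image_size = c(s[2], s[1]))
  inst <- derive_instances(lm, feature_box_size = feature_box_size)
  list(image = img, instances = inst)
}

#' Train the detector
#'
#' Gradient-accumulated batches of `batch_size` images per Adam step, the
#' warm-up + cosine schedule, and a per-iteration loss log. Aborts with a
#' diagnostic naming the offending term if any loss turns non-finite.
#'
#' @param model from [build_model()] (trained in place; also returned)
#' @param cases list of training cases, each with `$image` (H x W matrix),
#'   `$landmarks` ([landmarks13()]) and optionally `$config` (for the
#'   feature-box size); [generate_case()] output works directly
#' @param train_cfg a [train_config()]
#' @param feature_box_size tip/Carina feature-box side in pixels; default
#'   taken from the first case's generator config
#' @param log_path optional CSV path for the per-iteration loss log
#' @return list: `model`, `log` (data.frame of per-iteration losses)
#' @export
train <- function(model, cases, train_cfg = train_config(),
                  feature_box_size = NULL, log_path = NULL) {
  det_cfg <- model$config
  if (is.null(feature_box_size))
    feature_box_size <- cases[[1]]$config$feature_box_size
  if (is.null(feature_box_size))
    stop("feature_box_size must be given when cases carry no generator config")
  set.seed(train_cfg$seed)
  n <- length(cases)
  iters <- if (!is.null(train_cfg$iters)) train_cfg$iters
           else ceiling(train_cfg$epochs * n / train_cfg$batch_size)
  iters_per_epoch <- max(1, ceiling(n / train_cfg$batch_size))
  warmup_iters <- train_cfg$warmup_epochs * iters_per_epoch
  if (!is.null(train_cfg$iters))
    warmup_iters <- min(warmup_iters, max(1L, round(0.1 * iters)))
  opt <- adam_new(model$params, lr = train_cfg$lr)
  seg_on <- length(det_cfg$seg_classes) > 0L
  log <- vector("list", iters)
  order_idx <- integer(0)
  for (it in seq_len(iters)) {
    lr <- lr_schedule(it, iters, warmup_iters, train_cfg$lr)
    ag_zero_grad(model$params)
    acc <- c(cls = 0, reg = 0, ctr = 0, seg = 0, total = 0, n_pos = 0)
    for (bi in seq_len(train_cfg$batch_size)) {
      if (!length(order_idx)) order_idx <- sample.int(n)
      ci <- order_idx[1L]; order_idx <- order_idx[-1L]
      smp <- prepare_sample(cases[[ci]], det_cfg, train_cfg, feature_box_size)
      fwd <- model$forward(smp$image, with_seg = seg_on)
      geom <- lapply(fwd$levels, function(l)
        list(stride = l$stride, H = dim(l$cls$val)[1], W = dim(l$cls$val)[2]))
      tg <- assign_targets(smp$instances, geom, det_cfg$level_ranges)
      seg_mask <- if (seg_on)
        rasterize_mask(smp$instances, dim(fwd$seg$val)[2], dim(fwd$seg$val)[1],
                       det_cfg$seg_classes)
      else NULL
      ls <- detection_loss(fwd, tg, seg_mask, det_cfg)
      if (!all(is.finite(ls$breakdown))) {
        bad <- names(ls$breakdown)[!is.finite(ls$breakdown)]
        stop("non-finite loss at iteration ", it, " in term(s): ",
             paste(bad, collapse = ", "))
      }
      ag_backward(ag_scale(ls$total, 1 / train_cfg$batch_size))
      acc <- acc + ls$breakdown / train_cfg$batch_size
    }
    opt <- adam_step(opt, lr = lr)
    log[[it]] <- data.frame(iteration = it, lr = lr, t(acc))
    if (!is.null(train_cfg$log_every) && it %% train_cfg$log_every == 0L)
      message(sprintf("iter %4d  lr %.2e  total %.4f  (cls %.3f reg %.3f ctr %.3f seg %.3f)",
                      it, lr, acc["total"], acc["cls"], acc["reg"],
                      acc["ctr"], acc["seg"]))
  }
  log <- do.call(rbind, log)
  if (!is.null(log_path)) write.csv(log, log_path, row.names = FALSE)
  list(model = model, log = log)
}

#' Run inference on one image
#' @param model from [build_model()] / [load_checkpoint()]
#' @param image H x W intensity matrix
#' @param score_thresh,nms_iou decoding thresholds (default from the model
#'   config)
#' @return detections data.frame (see [decode_detections()])
#' @export
infer <- function(model, image, score_thresh = NULL, nms_iou = NULL) {
  cfg <- model$config
  fwd <- model$forward(image, with_seg = FALSE)
  decode_detections(lapply(fwd$levels, function(l)
    list(cls = l$cls$val, reg = l$reg$val, ctr = l$ctr$val, stride = l$stride)),
    image_size = c(ncol(image), nrow(image)),
    score_thresh = if (is.null(score_thresh)) cfg$score_thresh else score_thresh,
    nms_iou = if (is.null(nms_iou)) cfg$nms_iou else nms_iou)
}

#' Detect and post-process the ETT tip and Carina on one image
#' @inheritParams infer
#' @param conf_thresh,sigma post-process parameters (see
#'   [finalize_keypoints()])
#' @return a `keypoint_result`
#' @export
predict_keypoints <- function(model, image, score_thresh = NULL,
                              nms_iou = NULL, conf_thresh = 0.5,
                              sigma = NULL) {
  det <- infer(model, image, score_thresh, nms_iou)
  finalize_keypoints(det, c(ncol(image), nrow(image)),
                     conf_thresh = conf_thresh, sigma = sigma)
}

#' Evaluate a trained model over a list of cases
#' @param model trained model
#' @param cases list of cases with `$image`, `$landmarks`, `$pixel_spacing`
#' @param ... forwarded to [predict_keypoints()]
#' @return list: `per_image` (data.frame), `report` (an `eval_report`)
#' @export
evaluate_model <- function(model, cases, ...) {
  results <- lapply(cases, function(cs) {
    fp <- derive_feature_points(cs$landmarks)
    list(keypoints = predict_keypoints(model, cs$image, ...),
         gt_tip = fp$ett_tip, gt_carina = fp$carina,
         spacing = cs$pixel_spacing)
  })
  per_image <- evaluate_images(results)
  list(per_image = per_image, report = summarize_evaluation(per_image))
}

#' 5-fold cross-validation on a case list
#'
#' Trains one model per fold on the out-of-fold cases and evaluates on the
#' fold, then aggregates with [aggregate_folds()].
#' @param det_cfg a [detector_config()]
#' @param cases list of cases ([generate_case()] output)
#' @param folds integer fold id per case (e.g. from [assign_folds()])
#' @param train_cfg a [train_config()]
#' @param ... forwarded to [evaluate_model()]
#' @return list: per-fold `reports`, `aggregate` (means of headline metrics)
#' @export
crossval <- function(det_cfg, cases, folds, train_cfg = train_config(), ...) {
  stopifnot(length(folds) == length(cases))
  fold_ids <- sort(unique(folds))
  reports <- list()
  for (f in fold_ids) {
    set.seed(train_cfg$seed + f)
    model <- build_model(det_cfg)
    fit <- train(model, cases[folds != f], train_cfg)
    ev <- evaluate_model(fit$model, cases[folds == f], ...)
    reports[[as.character(f)]] <- ev$report
  }
  agg <- sapply(c("accuracy", "distance_mean", "distance_sd", "tip_mean",
                  "carina_mean"), function(field)
    aggregate_folds(vapply(reports, `[[`, numeric(1), field)))
  list(reports = reports, aggregate = agg)
}
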