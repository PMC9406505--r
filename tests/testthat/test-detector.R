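# Model assembly, target assignment and detection decoding.

test_that("centerness target matches the distance-ratio formula", {
  expect_equal(centerness_target(5, 3, 5, 3), 1)        # exact center
  expect_equal(centerness_target(1, 2, 3, 2), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(centerness_target(1, 2, 3, 2), 0.57735, tolerance = 1e-5)
})

test_that("desk model builds with the pyramid contract", {
  set.seed(41)
  dc <- detector_config("desk")
  model <- build_model(dc)
  expect_gt(count_parameters(model), 0)
  img <- matrix(runif(128 * 128), 128, 128)
  fwd <- model$forward(img)
  strides <- vapply(fwd$levels, `[[`, numeric(1), "stride")
  expect_equal(unname(strides), c(8, 16, 16, 32, 64))
  for (lv in fwd$levels) {
    d <- dim(lv$cls$val)
    expect_equal(d[1:2], dim(lv$ctr$val)[1:2])
    expect_equal(dim(lv$reg$val), c(d[1:2], 4L))
    expect_equal(d[3], 4L)
    expect_true(all(lv$reg$val > 0))     # distances decoded via exp
  }
  # P-levels all carry the neck width; seg output is 4x the P2 grid
  expect_true(all(vapply(fwd$pyramid, function(p) dim(p$val)[3], numeric(1)) ==
                    dc$neck_ch))
  expect_equal(dim(fwd$seg$val)[1:2], 4L * dim(fwd$pyramid$P2$val)[1:2])
  expect_equal(dim(fwd$seg$val)[3], length(dc$seg_classes) + 1L)
  # eval-mode determinism with fixed weights
  fwd2 <- model$forward(img)
  expect_identical(fwd$levels$P3$cls$val, fwd2$levels$P3$cls$val)
})

test_that("plain-detector baseline and seg ablations are constructible", {
  set.seed(42)
  base <- build_model(detector_config("desk", attention = "none"))
  withsa <- build_model(detector_config("desk", attention = "sa"))
  expect_gt(count_parameters(withsa), count_parameters(base))
  nofuse <- build_model(detector_config("desk", seg_fusion = FALSE))
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(dim(nofuse$forward(img)$seg$val)[3], 3L)
})

test_that("target assignment: positives, ranges, ambiguity and round trip", {
  lm <- fixture_landmarks()
  inst <- derive_instances(lm, feature_box_size = 60)
  geometry <- list(P3 = list(stride = 8L, H = 64L, W = 64L),
                   P4 = list(stride = 16L, H = 32L, W = 32L),
                   P5 = list(stride = 16L, H = 32L, W = 32L),
                   P6 = list(stride = 32L, H = 16L, W = 16L),
                   P7 = list(stride = 64L, H = 8L, W = 8L))
  ranges <- rbind(c(0, 64), c(64, 128), c(128, 256), c(256, 512), c(512, Inf))
  tg <- assign_targets(inst, geometry, ranges)
  n_pos <- sum(vapply(tg, function(t) sum(t$labels > 0), numeric(1)))
  expect_gt(n_pos, 0)
  for (li in seq_along(tg)) {
    t <- tg[[li]]
    pos <- which(t$labels > 0)
    if (!length(pos)) next
    # all four distances strictly positive, max within the level range
    for (p in pos) {
      rc <- cbind(row(t$labels)[p], col(t$labels)[p])
      d4 <- t$reg[rc[1], rc[2], ]
      expect_true(all(d4 > 0))
      expect_gt(max(d4), ranges[li, 1])
      expect_lte(max(d4), ranges[li, 2])
      # decoding the target distances reconstructs the GT box bit-exactly
      box <- inst$boxes[[t$labels[p]]]
      expect_identical(c(t$cx[p] - d4[1], t$cy[p] - d4[2],
                         t$cx[p] + d4[3], t$cy[p] + d4[4]), box)
      expect_equal(t$ctr[p], centerness_target(d4[1], d4[2], d4[3], d4[4]))
    }
    # smallest-area box wins where boxes overlap
    areas <- vapply(inst$boxes, ettloc:::bbox_area, numeric(1))
    for (p in pos) {
      cx <- t$cx[p]; cy <- t$cy[p]
      inside <- which(vapply(inst$boxes, function(b)
        cx > b[1] && cy > b[2] && cx < b[3] && cy < b[4], logical(1)))
      mx <- vapply(inside, function(bi) {
        b <- inst$boxes[[bi]]
        max(cx - b[1], cy - b[2], b[3] - cx, b[4] - cy)
      }, numeric(1))
      inside <- inside[mx > ranges[li, 1] & mx <= ranges[li, 2]]
      if (length(inside))
        expect_equal(t$labels[p], unname(inside[which.min(areas[inside])]))
    }
  }
  # empty instance set: every location is background
  tg0 <- assign_targets(NULL, geometry, ranges)
  expect_true(all(vapply(tg0, function(t) all(t$labels == 0L), logical(1))))
  # a location at a box's exact center has centerness 1
  sq <- structure(list(boxes = list(ETT = c(96, 96, 176, 176))),
                  class = "instance_set")
  tgc <- assign_targets(sq, geometry["P4"], rbind(c(0, Inf)))
  ctr_loc <- which(tgc[[1]]$cx == 136 & tgc[[1]]$cy == 136)
  expect_equal(tgc[[1]]$labels[ctr_loc], 1L)
  expect_equal(tgc[[1]]$ctr[ctr_loc], 1)
})

test_that("decoding recovers boxes, filters by score and suppresses duplicates", {
  # location (100,100) with l=t=r=b=10 decodes to the 20 px square around it
  out <- single_detection_output(100, 100, c(10, 10, 10, 10))
  det <- decode_detections(out, c(256, 256), score_thresh = 0.5)
  expect_equal(nrow(det), 1L)
  expect_equal(unname(unlist(det[1, c("x1", "y1", "x2", "y2")])),
               c(90, 90, 110, 110))
  expect_equal(det$class, "ETT_tip")
  expect_equal(det$score, det$score_cls * det$score_ctr)
  # decoded box contains its source location
  expect_true(det$x1 < 100 && det$x2 > 100 && det$y1 < 100 && det$y2 > 100)
  # score_thresh = 1 empties the output
  expect_equal(nrow(decode_detections(out, c(256, 256), score_thresh = 1)), 0L)
  # two near-identical boxes: NMS keeps the higher-scored one
  out2 <- out
  out2[[1]]$cls[13, 14, 2] <- 1    # overlapping, lower score
  out2[[1]]$ctr[13, 14, 1] <- 1
  out2[[1]]$reg[13, 14, ] <- c(18, 14, 2, 6)
  det2 <- decode_detections(out2, c(256, 256), score_thresh = 0.2,
                            nms_iou = 0.5)
  expect_equal(nrow(det2), 1L)
  expect_equal(det2$score_cls[1], 1 / (1 + exp(-20)), tolerance = 1e-9)
})

test_that("parameter and FLOP accounting follow convolution arithmetic", {
  conv <- ettloc:::nn_conv(16L, 16L, k = 3L)
  expect_equal(ettloc:::n_trainable(ettloc:::collect_params(conv$params)),
               3 * 3 * 16 * 16 + 16)   # 2,320
  set.seed(43)
  model <- build_model(detector_config("desk"))
  f224 <- count_flops(model, 224L)
  f448 <- count_flops(model, 448L)
  expect_gt(f224, 0)
  expect_gt(f448 / f224, 3.5)
  expect_lt(f448 / f224, 4.5)
  # parameter count does not depend on the input size
  expect_equal(count_parameters(model), count_parameters(model))
})

test_that("checkpoints round-trip weights and refuse mismatched configs", {
  set.seed(44)
  model <- build_model(detector_config("desk"))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  model2 <- load_checkpoint(ck)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(infer(model, img), infer(model2, img))
  # tamper with the stored config: rebuild must refuse
  bad <- readRDS(ck)
  bad$config$neck_ch <- 24L
  ck2 <- tempfile(fileext = ".rds")
  saveRDS(bad, ck2)
  expect_error(load_checkpoint(ck2), "mismatch")
})
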