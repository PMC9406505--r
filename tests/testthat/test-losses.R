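test_that("focal loss matches its closed form and limits", {
  # direct evaluation at (y=1, p=0.9, a=0.25, gamma=2)
  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2), 2.6342e-4,
               tolerance = 1e-3)
  # gamma = 0, alpha = 0.5 reduces to half the cross-entropy
  set.seed(31)
  p <- runif(20, 0.05, 0.95); y <- rbinom(20, 1, 0.5)
  ce <- sum(-(y * log(p) + (1 - y) * log(1 - p))) / max(1, sum(y == 1))
  expect_equal(focal_loss(p, y, alpha = 0.5, gamma = 0), 0.5 * ce,
               tolerance = 1e-9)
  # monotone decreasing in p_t
  ps <- seq(0.05, 0.999, length.out = 50)
  ls <- vapply(ps, function(pp) focal_loss(pp, 1, 0.25, 2), numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_lt(tail(ls, 1), 1e-5)
})

test_that("GIoU matches the analytic cases and a rasterization oracle", {
  a <- c(10, 20, 110, 80)
  expect_equal(giou(a, a), 1)
  expect_equal(giou_loss(a, a), 0)
  # disjoint unit squares two apart: IoU 0, C area 9, union 2
  expect_equal(giou(c(0, 0, 1, 1), c(2, 2, 3, 3)), -7 / 9, tolerance = 1e-12)
  expect_equal(giou_loss(c(0, 0, 1, 1), c(2, 2, 3, 3)), 1 + 7 / 9,
               tolerance = 1e-4)
  # nested boxes: enclosing box = outer box, so GIoU = IoU
  outer_b <- c(0, 0, 100, 100); inner_b <- c(20, 20, 60, 70)
  expect_equal(giou(outer_b, inner_b),
               ettloc:::box_iou(outer_b, inner_b), tolerance = 1e-12)
  # Monte-Carlo: analytic IoU/GIoU vs pixel rasterization on integer boxes
  set.seed(32)
  for (i in 1:100) {
    mk <- function() {
      x <- sort(sample(0:300, 2)); y <- sort(sample(0:300, 2))
      if (x[1] == x[2]) x[2] <- x[2] + 1
      if (y[1] == y[2]) y[2] <- y[2] + 1
      c(x[1], y[1], x[2], y[2])
    }
    A <- mk(); B <- mk()
    oracle <- raster_giou(A, B)
    expect_equal(giou(A, B), oracle$giou, tolerance = 1e-2)
    expect_equal(ettloc:::box_iou(A, B), oracle$iou, tolerance = 1e-2)
  }
})

test_that("GIoU loss is bounded, symmetric and translation invariant", {
  set.seed(33)
  for (i in 1:50) {
    A <- c(sort(runif(2, 0, 200)), sort(runif(2, 0, 200)))[c(1, 3, 2, 4)]
    B <- c(sort(runif(2, 0, 200)), sort(runif(2, 0, 200)))[c(1, 3, 2, 4)]
    l <- giou_loss(A, B)
    expect_gte(l, 0); expect_lte(l, 2)
    expect_equal(l, giou_loss(B, A), tolerance = 1e-12)
    sh <- rep(runif(2, -50, 50), 2)
    expect_equal(giou_loss(A + sh, B + sh), l, tolerance = 1e-9)
  }
})

test_that("centerness loss matches BCE and guards the empty case", {
  expect_equal(centerness_loss(c(1, 0, 1), c(1, 0, 1)), 0, tolerance = 1e-5)
  expect_equal(centerness_loss(0.5, 1), log(2), tolerance = 1e-6)
  expect_equal(centerness_loss(numeric(0), numeric(0)), 0)
})

test_that("segmentation loss limits: perfect, empty-prediction and lambda", {
  H <- 8L; W <- 8L
  mask <- matrix(0L, H, W); mask[3:6, 3:6] <- 1L
  # near-one-hot logits for the truth
  logits <- array(-30, dim = c(H, W, 3))
  logits[, , 1][mask == 0L] <- 30
  logits[, , 2][mask == 1L] <- 30
  perfect <- segmentation_loss(logits, mask)
  expect_lt(perfect$total, 1e-6)
  # all-background prediction vs half-foreground mask: Dice term -> 1
  bg <- array(-30, dim = c(H, W, 3)); bg[, , 1] <- 30
  miss <- segmentation_loss(bg, mask)
  expect_equal(miss$dice, 1, tolerance = 1e-3)
  expect_gt(miss$ce, 1)
  # lambda = 0 leaves pure Dice
  expect_equal(segmentation_loss(bg, mask, lambda = 0)$total, miss$dice)
})

test_that("autodiff loss terms agree with the numeric reference forms", {
  set.seed(34)
  # focal: random logits over 2 levels, 4 classes
  labs <- list(matrix(sample(0:4, 12, TRUE), 3, 4),
               matrix(sample(0:4, 4, TRUE), 2, 2))
  cls <- list(ettloc:::ag_const(array(rnorm(3 * 4 * 4), dim = c(3, 4, 4))),
              ettloc:::ag_const(array(rnorm(2 * 2 * 4), dim = c(2, 2, 4))))
  npos <- sum(sapply(labs, function(l) sum(l > 0)))
  agf <- ettloc:::ag_focal_loss(cls, labs, 4L, 0.25, 2, npos)
  pref <- unlist(lapply(seq_along(cls), function(i) {
    p <- 1 / (1 + exp(-as.numeric(cls[[i]]$val)))
    y <- as.numeric(outer(as.integer(labs[[i]]), 1:4, `==`))
    focal_loss(p, y, 0.25, 2, n_pos = npos) }))
  expect_equal(agf$val, sum(pref), tolerance = 1e-9)

  # GIoU: predictions vs ground-truth boxes around shared centers
  cx <- c(50, 120); cy <- c(60, 90)
  pl <- ettloc:::ag_const(c(10, 5)); pt <- ettloc:::ag_const(c(12, 6))
  pr <- ettloc:::ag_const(c(9, 7)); pb <- ettloc:::ag_const(c(11, 8))
  gt <- rbind(c(45, 50, 62, 70), c(110, 80, 130, 100))
  agg <- ettloc:::ag_giou_loss(list(l = pl, t = pt, r = pr, b = pb), cx, cy, gt)
  ref <- mean(c(giou_loss(c(40, 48, 59, 71), gt[1, ]),
                giou_loss(c(115, 84, 127, 98), gt[2, ])))
  expect_equal(agg$val, ref, tolerance = 1e-12)

  # centerness BCE with logits
  z <- rnorm(6); tgt <- runif(6)
  agc <- ettloc:::ag_centerness_loss(ettloc:::ag_const(z), tgt)
  expect_equal(agc$val, centerness_loss(1 / (1 + exp(-z)), tgt),
               tolerance = 1e-6)

  # segmentation
  lg <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  mk <- matrix(sample(0:2, 20, TRUE), 5, 4)
  ags <- ettloc:::ag_segmentation_loss(ettloc:::ag_const(lg), mk)
  ref2 <- segmentation_loss(lg, mk)
  expect_equal(ags$total$val, ref2$total, tolerance = 1e-9)
})
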