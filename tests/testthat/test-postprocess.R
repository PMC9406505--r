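mk_det <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(class = r$class, x1 = r$box[1], y1 = r$box[2],
               x2 = r$box[3], y2 = r$box[4],
               score_cls = r$score, score_ctr = 1, score = r$score)
  }))
}

test_that("best_box takes the top score with area and index tie-breaks", {
  det <- mk_det(list(class = "ETT", box = c(0, 0, 10, 10), score = 0.3),
                list(class = "ETT", box = c(5, 5, 30, 30), score = 0.9),
                list(class = "ETT", box = c(1, 1, 20, 20), score = 0.5))
  expect_equal(best_box(det, "ETT")$score, 0.9)
  expect_null(best_box(det, "Carina"))
  # score tie: the smaller-area box wins
  det2 <- mk_det(list(class = "Carina", box = c(0, 0, 20, 20), score = 0.7),
                 list(class = "Carina", box = c(0, 0, 10, 10), score = 0.7))
  expect_equal(unname(unlist(best_box(det2, "Carina")[, c("x1", "x2")])), c(0, 10))
  # full tie: earlier row wins
  det3 <- mk_det(list(class = "Carina", box = c(0, 0, 10, 10), score = 0.7),
                 list(class = "Carina", box = c(5, 5, 15, 15), score = 0.7))
  expect_equal(best_box(det3, "Carina")$x1, 0)
})

test_that("gaussian_weight follows the squared-exponential profile", {
  mu <- c(100, 100)
  expect_equal(gaussian_weight(mu, mu, 50), 1)
  expect_equal(gaussian_weight(c(150, 100), mu, 50), exp(-1 / 2),
               tolerance = 1e-12)
  expect_equal(gaussian_weight(c(100, 250), mu, 50), exp(-9 / 2),
               tolerance = 1e-12)
  expect_equal(gaussian_weight(c(100, 250), mu, 50), 0.0111, tolerance = 1e-3)
  ds <- seq(0, 300, by = 10)
  ws <- vapply(ds, function(d) gaussian_weight(mu + c(d, 0), mu, 50), numeric(1))
  expect_true(all(diff(ws) < 0))
  expect_error(gaussian_weight(mu, mu, 0), "sigma")
})

test_that("Gaussian re-scoring prefers candidates near the parent prior", {
  sigma <- 40
  # distances chosen so the far candidate gets weight 0.1, the near one 0.9
  d_far <- sigma * sqrt(2 * log(1 / 0.1))
  d_near <- sigma * sqrt(2 * log(1 / 0.9))
  prior <- c(128, 128)
  sq <- function(ctr, half = 10) c(ctr - half, ctr + half)[c(1, 3, 2, 4)]
  box_at <- function(ctr) c(ctr[1] - 10, ctr[2] - 10, ctr[1] + 10, ctr[2] + 10)
  det <- mk_det(
    list(class = "ETT", box = c(108, 28, 148, 128), score = 0.95),
    list(class = "ETT_tip", box = box_at(prior + c(d_far, 0)), score = 0.8),
    list(class = "ETT_tip", box = box_at(prior + c(0, d_near)), score = 0.6))
  # parent ETT box centered on the prior
  det[1, c("x1", "y1", "x2", "y2")] <- c(prior[1] - 20, prior[2] - 100,
                                         prior[1] + 20, prior[2] + 100)
  kp <- finalize_keypoints(det, c(256, 256), conf_thresh = 0.5, sigma = sigma)
  # re-scores: 0.8 x 0.1 = 0.08 vs 0.6 x 0.9 = 0.54 -> near candidate wins
  expect_equal(kp$ett_tip$point, prior + c(0, d_near))
  expect_equal(kp$ett_tip$provenance, "tip_box_center")
})

test_that("weak tip falls back to the ETT box bottom-edge midpoint", {
  det <- mk_det(list(class = "ETT", box = c(10, 10, 30, 90), score = 0.9),
                list(class = "ETT_tip", box = c(14, 80, 26, 92), score = 0.3))
  kp <- finalize_keypoints(det, c(512, 512), conf_thresh = 0.5)
  expect_equal(kp$ett_tip$point, c(20, 90))
  expect_equal(kp$ett_tip$provenance, "ett_box_bottom_mid")
  # weak Carina falls back to the bifurcation box center
  det2 <- mk_det(list(class = "tracheal_bifurcation", box = c(100, 100, 180, 160),
                      score = 0.8),
                 list(class = "Carina", box = c(120, 120, 140, 140), score = 0.2))
  kp2 <- finalize_keypoints(det2, c(512, 512), conf_thresh = 0.5)
  expect_equal(kp2$carina$point, c(140, 130))
  expect_equal(kp2$carina$provenance, "bifurcation_box_center")
  # a weak tip that still beats its parent keeps its own center
  det3 <- mk_det(list(class = "ETT", box = c(10, 10, 30, 90), score = 0.2),
                 list(class = "ETT_tip", box = c(14, 80, 26, 92), score = 0.3))
  kp3 <- finalize_keypoints(det3, c(512, 512), conf_thresh = 0.5)
  expect_equal(kp3$ett_tip$provenance, "tip_box_center")
  expect_equal(kp3$ett_tip$point, c(20, 86))
})

test_that("missing parents center the prior on the image; empty input -> none", {
  # no ETT box: two equidistant-from-center candidates keep their raw order
  det <- mk_det(list(class = "ETT_tip", box = c(100, 100, 120, 120), score = 0.9),
                list(class = "ETT_tip", box = c(140, 140, 160, 160), score = 0.6))
  kp <- finalize_keypoints(det, c(256, 256), conf_thresh = 0.5)
  # both candidates sit symmetric about the (128, 128) prior: equal weights,
  # so the higher raw score must win
  expect_equal(kp$ett_tip$point, c(110, 110))
  empty <- decode_detections(list(), c(256, 256))
  kp0 <- finalize_keypoints(empty, c(256, 256))
  expect_equal(kp0$ett_tip$provenance, "none")
  expect_equal(kp0$carina$provenance, "none")
  expect_true(all(is.na(kp0$ett_tip$point)))
})

test_that("at most one tip and one carina survive adversarial inputs", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(0:30, 1)
    det <- if (n == 0) decode_detections(list(), c(256, 256)) else
      do.call(mk_det, lapply(seq_len(n), function(i) {
        ctr <- runif(2, 20, 236)
        list(class = sample(c("ETT", "ETT_tip", "tracheal_bifurcation",
                              "Carina"), 1),
             box = c(ctr - runif(2, 5, 20), ctr + runif(2, 5, 20))[c(1, 3, 2, 4)],
             score = runif(1))
      }))
    kp <- finalize_keypoints(det, c(256, 256))
    expect_length(kp$ett_tip$point, 2L)
    expect_length(kp$carina$point, 2L)
    expect_true(kp$ett_tip$provenance %in%
                  c("tip_box_center", "ett_box_bottom_mid", "none"))
    expect_true(kp$carina$provenance %in%
                  c("carina_box_center", "bifurcation_box_center", "none"))
  }
})

test_that("a single confident candidate is returned unchanged (idempotence)", {
  det <- mk_det(list(class = "Carina", box = c(100, 120, 140, 150), score = 0.8))
  kp <- finalize_keypoints(det, c(256, 256), conf_thresh = 0.5)
  expect_equal(kp$carina$point, c(120, 135))
  expect_equal(kp$carina$confidence, 0.8)
})
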