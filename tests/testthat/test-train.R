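# Training orchestration: schedule, transforms, determinism, cross-validation
# plumbing and the file-based CLI round trip.

test_that("learning-rate schedule: warm-up ramp then cosine decay to zero", {
  base <- 1e-4; total <- 1000; warm <- 100
  expect_equal(lr_schedule(1, total, warm, base), base / warm)
  expect_equal(lr_schedule(warm, total, warm, base), base)
  expect_equal(lr_schedule(total, total, warm, base), 0, tolerance = 1e-12)
  mid <- lr_schedule((total + warm) / 2, total, warm, base)
  expect_equal(mid, base / 2, tolerance = 1e-6)
  lrs <- vapply(seq(warm, total), lr_schedule, numeric(1),
                total_iters = total, warmup_iters = warm, base_lr = base)
  expect_true(all(diff(lrs) <= 0))
})

test_that("rotation moves image content and landmarks together", {
  img <- matrix(0, 64, 64)
  img[20 + 1, 40 + 1] <- 1                     # bright pixel at (x=40, y=20)
  pts <- rbind(c(40, 20), c(31.5, 31.5))
  rot <- rotate_case(img, pts, 90)             # quarter turn
  # the image center is a fixed point
  expect_equal(rot$pts[2, ], c(31.5, 31.5))
  # the bright pixel lands where the transformed landmark says
  hit <- which(rot$img == 1, arr.ind = TRUE)
  expect_equal(unname(hit[1, ]), c(round(rot$pts[1, 2]) + 1,
                                   round(rot$pts[1, 1]) + 1))
  # zero rotation is the identity
  rot0 <- rotate_case(img, pts, 0)
  expect_identical(rot0$img, img)
  expect_equal(rot0$pts, pts)
})

test_that("resize scales landmarks with the raster", {
  img <- matrix(runif(64 * 64), 64, 64)
  pts <- rbind(c(10, 20), c(40, 50))
  rs <- resize_case(img, pts, 0.5)
  expect_equal(dim(rs$img), c(32L, 32L))
  expect_equal(rs$pts, pts * 0.5)
})

test_that("polygon rasterization fills the expected pixels", {
  inst <- structure(list(polygons = list(
    ETT = rbind(c(2, 2), c(7, 2), c(7, 9), c(2, 9)),
    tracheal_bifurcation = rbind(c(10, 10), c(14, 10), c(12, 14)))),
    class = "instance_set")
  mask <- rasterize_mask(inst, 20L, 20L)
  # interior of the rectangle is class 1
  expect_equal(mask[5 + 1, 5 + 1], 1L)
  expect_equal(mask[3 + 1, 3 + 1], 1L)
  expect_equal(mask[1 + 1, 1 + 1], 0L)
  # triangle apex region is class 2
  expect_equal(mask[11 + 1, 12 + 1], 2L)
  expect_equal(mask[12 + 1, 12 + 1], 2L)
  # rectangle pixel count close to its area
  expect_equal(sum(mask == 1L), 35, tolerance = 8)
})

test_that("micro-training is seed-deterministic and logs decreasing losses", {
  cfg <- synth_config(image_size = 96L)
  cases <- lapply(1:4, function(i) generate_case(cfg, seed = 300 + i))
  dc <- detector_config("desk")
  tc <- train_config("desk", iters = 4L, log_every = NULL)
  run <- function() {
    set.seed(9)
    model <- build_model(dc)
    train(model, cases, tc)
  }
  a <- run(); b <- run()
  expect_equal(a$log$total, b$log$total, tolerance = 1e-12)
  expect_true(all(is.finite(a$log$total)))
  expect_named(a$log, c("iteration", "lr", "cls", "reg", "ctr", "seg",
                        "total", "n_pos"))
  # inference is idempotent
  img <- cases[[1]]$image
  expect_identical(infer(a$model, img), infer(a$model, img))
})

test_that("cross-validation trains per fold and sizes test sets correctly", {
  cfg <- synth_config(image_size = 96L)
  set.seed(71)
  cases <- lapply(1:10, function(i) generate_case(cfg, seed = 400 + i))
  folds <- assign_folds(vapply(cases, `[[`, character(1), "label"), 5L)
  expect_equal(unname(table(folds)), rep(2L, 5), ignore_attr = TRUE)
  dc <- detector_config("desk")
  tc <- train_config("desk", iters = 2L, log_every = NULL)
  cv <- crossval(dc, cases, folds, tc, score_thresh = 0.3)
  expect_length(cv$reports, 5L)
  expect_true(all(vapply(cv$reports, `[[`, numeric(1), "n") == 2))
  expect_equal(unname(cv$aggregate["accuracy"]),
               mean(vapply(cv$reports, `[[`, numeric(1), "accuracy")))
})

test_that("the CLI surface round-trips through files only", {
  dir <- tempfile("clids")
  cfg <- synth_config(image_size = 96L)
  generate_dataset(cfg, 4L, dir, seed = 12)
  ck <- tempfile(fileext = ".rds")
  pred <- tempfile(fileext = ".json")
  kp <- tempfile(fileext = ".json")
  expect_equal(cli_main(c("synth", "--n", "3", "--size", "96",
                          "--out", tempfile("clisynth"))), 0L,
               ignore_attr = TRUE)
  suppressMessages(cli_main(c("train", "--data", dir, "--profile", "desk",
                              "--iters", "2", "--checkpoint", ck)))
  expect_true(file.exists(ck))
  cli_main(c("infer", "--checkpoint", ck, "--data", dir, "--out", pred))
  expect_true(file.exists(pred))
  cli_main(c("postprocess", "--predictions", pred, "--out", kp,
             "--width", "96", "--height", "96"))
  expect_true(file.exists(kp))
  ev <- evaluate_keypoints_file(kp, dir)
  expect_equal(nrow(ev$per_image), 4L)
  out <- capture.output(cli_main(c("count-params", "--profile", "desk")))
  expect_true(any(grepl("parameters:", out)))
})

test_that("augmentation keeps every landmark inside the frame", {
  cfg <- synth_config(image_size = 96L)
  cs <- generate_case(cfg, seed = 314)
  tc <- train_config("desk", augment = TRUE)
  set.seed(15)
  for (i in 1:10) {
    aug <- ettloc:::augment_case(cs$image, cs$landmarks$points, tc)
    smp <- ettloc:::prepare_sample(cs, detector_config("desk"), tc,
                                   feature_box_size = cfg$feature_box_size)
    expect_true(all(smp$instances$boxes$ETT[1:2] >= -1))
    expect_true(all(smp$image >= 0 & smp$image <= 1))
  }
})
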