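# The autodiff engine is the substrate of the detector; these checks pin the
# analytic gradients of every structured op against central finite
# differences on tiny inputs.

expect_grad_matches <- function(node_fn, value_fn, x, tol = 1e-6) {
  xn <- ettloc:::ag_const(x)
  xn$requires_grad <- TRUE
  out <- node_fn(xn)
  wts <- array(seq_along(out$val) %% 7 - 3, dim = dim(out$val))
  loss <- ettloc:::ag_sum(ettloc:::ag_mul(out, ettloc:::ag_const(wts)))
  ettloc:::ag_backward(loss)
  fn <- function(xv) sum(value_fn(xv) * wts)
  expect_lt(max(abs(xn$grad - num_grad(fn, x))), tol)
}

test_that("convolution gradients match finite differences (stride/pad/dilation)", {
  set.seed(101)
  for (cfg in list(list(k = 3L, s = 1L, p = 2L, d = 2L),
                   list(k = 3L, s = 2L, p = 1L, d = 1L),
                   list(k = 1L, s = 1L, p = 0L, d = 1L))) {
    x <- array(rnorm(6 * 7 * 3), dim = c(6, 7, 3))
    w <- array(rnorm(cfg$k^2 * 3 * 2) * 0.4, dim = c(cfg$k, cfg$k, 3, 2))
    b <- rnorm(2)
    wn <- ettloc:::ag_param(w); bn <- ettloc:::ag_param(b)
    expect_grad_matches(
      function(xn) ettloc:::ag_conv2d(xn, wn, bn, cfg$s, cfg$p, cfg$d),
      function(xv) ettloc:::.conv2d_fwd(xv, w, b, cfg$s, cfg$p, cfg$d),
      x)
    # weight gradient
    xn <- ettloc:::ag_const(x)
    out <- ettloc:::ag_conv2d(xn, wn, bn, cfg$s, cfg$p, cfg$d)
    wts <- array(seq_along(out$val) %% 5 - 2, dim = dim(out$val))
    ettloc:::ag_zero_grad(list(wn, bn))
    ettloc:::ag_backward(ettloc:::ag_sum(ettloc:::ag_mul(out, ettloc:::ag_const(wts))))
    fw <- function(wv) sum(ettloc:::.conv2d_fwd(x, wv, b, cfg$s, cfg$p, cfg$d) * wts)
    expect_lt(max(abs(wn$grad - num_grad(fw, w))), 1e-6)
  }
})

test_that("normalization, pooling, upsampling and softmax gradients are exact", {
  set.seed(102)
  x <- array(rnorm(5 * 4 * 6), dim = c(5, 4, 6))
  gam <- ettloc:::ag_param(rnorm(6) * 0.2 + 1)
  bet <- ettloc:::ag_param(rnorm(6) * 0.2)
  expect_grad_matches(
    function(xn) ettloc:::ag_groupnorm(xn, gam, bet, groups = 2L),
    function(xv) ettloc:::ag_groupnorm(ettloc:::ag_const(xv), gam, bet, groups = 2L)$val,
    x, tol = 1e-5)
  expect_grad_matches(
    function(xn) ettloc:::ag_maxpool(xn, 3L, 2L, 1L),
    function(xv) ettloc:::.maxpool2d_fwd(xv, 3L, 2L, 1L)$out, x)
  expect_grad_matches(
    function(xn) ettloc:::ag_upsample_nearest(xn, 3L),
    function(xv) ettloc:::ag_upsample_nearest(ettloc:::ag_const(xv), 3L)$val, x)
  for (type in c("avg", "max")) {
    expect_grad_matches(
      function(xn) ettloc:::ag_adaptive_pool(xn, c(3L, 3L), type),
      function(xv) ettloc:::ag_adaptive_pool(ettloc:::ag_const(xv), c(3L, 3L), type)$val,
      x)
    expect_grad_matches(
      function(xn) ettloc:::ag_chan_group_pool(xn, 3L, type),
      function(xv) ettloc:::ag_chan_group_pool(ettloc:::ag_const(xv), 3L, type)$val,
      x)
  }
  x1 <- array(rnorm(4 * 5 * 1), dim = c(4, 5, 1))
  expect_grad_matches(
    function(xn) ettloc:::ag_spatial_softmax(xn),
    function(xv) ettloc:::ag_spatial_softmax(ettloc:::ag_const(xv))$val, x1)
  expect_grad_matches(
    function(xn) ettloc:::ag_softmax_c(xn),
    function(xv) ettloc:::ag_softmax_c(ettloc:::ag_const(xv))$val, x)
})

test_that("elementwise primitives and reductions back-propagate correctly", {
  set.seed(103)
  x <- rnorm(17)
  y <- rnorm(17)
  # composite expression touching most primitives
  f_node <- function(xn) {
    a <- ettloc:::ag_mul(ettloc:::ag_sigmoid(xn), y)
    b <- ettloc:::ag_softplus(ettloc:::ag_scale(xn, -1.3))
    cc <- ettloc:::ag_pmax(a, b)
    dd <- ettloc:::ag_div(cc, ettloc:::ag_add(ettloc:::ag_pow(xn, 2), 1.7))
    ettloc:::ag_reshape(ettloc:::ag_sqrt(ettloc:::ag_add(dd, 3)), c(17, 1, 1))
  }
  f_val <- function(xv) {
    a <- (1 / (1 + exp(-xv))) * y
    b <- log1p(exp(-1.3 * xv))
    cc <- pmax(a, b)
    dd <- cc / (xv^2 + 1.7)
    array(sqrt(dd + 3), dim = c(17, 1, 1))
  }
  expect_grad_matches(f_node, f_val, x, tol = 1e-5)
})

test_that("gather scatter-adds repeated indices and concat splits gradients", {
  x <- ettloc:::ag_const(c(1, 2, 3, 4))
  x$requires_grad <- TRUE
  g <- ettloc:::ag_gather(x, c(2L, 2L, 4L))
  expect_equal(g$val, c(2, 2, 4))
  ettloc:::ag_backward(ettloc:::ag_sum(ettloc:::ag_mul(g, c(10, 1, 5))))
  expect_equal(as.numeric(x$grad), c(0, 11, 0, 5))

  a <- ettloc:::ag_const(c(1, 2)); a$requires_grad <- TRUE
  b <- ettloc:::ag_const(c(3, 4, 5)); b$requires_grad <- TRUE
  cc <- ettloc:::ag_cat_vec(list(a, b))
  expect_equal(cc$val, 1:5 * 1)
  ettloc:::ag_backward(ettloc:::ag_sum(ettloc:::ag_mul(cc, c(1, 2, 3, 4, 5))))
  expect_equal(as.numeric(a$grad), c(1, 2))
  expect_equal(as.numeric(b$grad), c(3, 4, 5))
})

test_that("shared nodes accumulate gradients along both paths", {
  x <- ettloc:::ag_const(c(1.5, -0.5))
  x$requires_grad <- TRUE
  y <- ettloc:::ag_add(ettloc:::ag_mul(x, x), ettloc:::ag_scale(x, 3))  # x^2 + 3x
  ettloc:::ag_backward(ettloc:::ag_sum(y))
  expect_equal(as.numeric(x$grad), 2 * c(1.5, -0.5) + 3)
})
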