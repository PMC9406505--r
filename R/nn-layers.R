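# Layer modules over the autodiff engine. A module is a list with a $forward
# closure and a $params list of parameter nodes; composite modules nest and
# parameters are collected recursively. Initialization follows common
# detector practice: He-normal conv weights, zero biases, unit norm gains.

nn_rnorm <- function(n, sd) stats::rnorm(n, mean = 0, sd = sd)

#' 2-D convolution module
#' @noRd
nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, dilation = 1L,
                    pad = NULL, bias = TRUE, init_sd = NULL, bias_init = 0) {
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L  # "same" for stride 1
  if (is.null(init_sd)) init_sd <- sqrt(2 / (k * k * in_ch))
  w <- ag_param(array(nn_rnorm(k * k * in_ch * out_ch, init_sd),
                      dim = c(k, k, in_ch, out_ch)))
  b <- ag_param(rep(bias_init, out_ch))
  b$requires_grad <- bias
  m <- list(
    kind = "conv", in_ch = in_ch, out_ch = out_ch, k = k, stride = stride,
    dilation = dilation, pad = pad,
    params = if (bias) list(w = w, b = b) else list(w = w),
    w = w, b = b)
  m$forward <- function(x) ag_conv2d(x, w, b, stride = stride, pad = pad,
                                     dilation = dilation)
  m
}

#' Per-sample group normalization module (instance norm when groups == C)
#' @noRd
nn_norm <- function(ch, groups = NULL, frozen = FALSE) {
  if (is.null(groups)) groups <- ch  # instance-style by default
  groups <- min(groups, ch)
  while (ch %% groups != 0L) groups <- groups - 1L
  gamma <- ag_param(rep(1, ch))
  beta <- ag_param(rep(0, ch))
  if (frozen) {
    gamma$requires_grad <- FALSE
    beta$requires_grad <- FALSE
  }
  m <- list(kind = "norm", ch = ch, groups = groups,
            params = list(gamma = gamma, beta = beta))
  m$forward <- function(x) ag_groupnorm(x, gamma, beta, groups = groups)
  m
}

#' conv + norm + ReLU block
#' @noRd
nn_cnr <- function(in_ch, out_ch, k = 3L, stride = 1L, dilation = 1L,
                   norm_groups = NULL, frozen_norm = FALSE, relu = TRUE) {
  conv <- nn_conv(in_ch, out_ch, k = k, stride = stride, dilation = dilation,
                  bias = FALSE)
  norm <- nn_norm(out_ch, groups = norm_groups, frozen = frozen_norm)
  m <- list(kind = "cnr", params = list(conv = conv$params, norm = norm$params))
  m$forward <- function(x) {
    y <- norm$forward(conv$forward(x))
    if (relu) ag_relu(y) else y
  }
  m
}

nn_linear <- function(in_n, out_n, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / in_n)
  w <- ag_param(matrix(nn_rnorm(out_n * in_n, init_sd), nrow = out_n))
  b <- ag_param(rep(0, out_n))
  m <- list(kind = "linear", params = list(w = w, b = b))
  m$forward <- function(x) ag_linear(x, w, b)
  m
}

nn_sequential <- function(...) {
  mods <- list(...)
  m <- list(kind = "seq", mods = mods,
            params = lapply(mods, function(mm) mm$params))
  m$forward <- function(x) {
    for (mm in mods) x <- mm$forward(x)
    x
  }
  m
}

# flatten a nested $params structure into a flat named list of ag nodes
collect_params <- function(x, prefix = "") {
  if (is_ag(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    }
    return(out)
  }
  list()
}

n_trainable <- function(params) {
  sum(vapply(params, function(p) if (isTRUE(p$requires_grad)) length(p$val) else 0L,
             numeric(1)))
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) array(0, dim = dim_or_len(p$val))),
       v = lapply(params, function(p) array(0, dim = dim_or_len(p$val))),
       t = 0L)
}

adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (!isTRUE(p$requires_grad) || is.null(p$grad)) next
    g <- p$grad
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    nv <- p$val - lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    dim(nv) <- dim(p$val)   # keep scalar params dimensionless
    p$val <- nv
  }
  opt
}

# serialize / restore parameter values (checkpointing)
params_state <- function(params) lapply(params, function(p) p$val)

params_restore <- function(params, state) {
  stopifnot(length(params) == length(state))
  nm <- names(params)
  for (i in seq_along(params)) {
    if (!identical(dim_or_len(params[[i]]$val), dim_or_len(state[[i]])))
      stop("checkpoint/config mismatch at parameter ", nm[i])
    params[[i]]$val <- state[[i]]
  }
  invisible(params)
}
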