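# Coarse-to-fine attention: global-modelling attention (GA) captures
# long-range context through a cross-region and an adjacent-region branch of
# dilated/point-wise convolutions; scale attention (SA) rescales the input by
# a single spatial weight map distilled from grouped channel pooling and a
# squeeze-and-excitation pair; CTFA chains GA -> point-wise smoothing -> SA.
#
# Every convolution is followed by per-sample normalization and ReLU except
# the two logits-producing convolutions (the 1x1 conv emitting the spatial
# weight in SA, and GA's terminal dilated conv when the softmax ablation is
# on, where the weight must stay unsquashed).

#' Global-modelling attention module
#'
#' Two branches over the input `Fin` (both keep C channels): the cross-region
#' branch applies a 3x3 dilated convolution (rate 3) then a point-wise
#' convolution; the adjacent-region branch applies them in the opposite
#' order. The concatenated 2C-channel map is reduced by a point-wise
#' convolution and expanded by a 3x3 dilated convolution (rate 2). By default
#' no terminal softmax is applied; `softmax = TRUE` restores the
#' per-channel spatial softmax for the ablation variant.
#'
#' @param channels input/output channel count C
#' @param softmax logical; apply a terminal per-channel spatial softmax
#' @return module list with `$forward` and `$params`
#' @export
nn_ga <- function(channels, softmax = FALSE) {
  C <- channels
  cr1 <- nn_cnr(C, C, k = 3L, dilation = 3L)   # cross-region: dilated then 1x1
  cr2 <- nn_cnr(C, C, k = 1L)
  ar1 <- nn_cnr(C, C, k = 1L)                  # adjacent-region: 1x1 then dilated
  ar2 <- nn_cnr(C, C, k = 3L, dilation = 3L)
  fuse1 <- nn_cnr(2L * C, C, k = 1L)
  fuse2 <- if (softmax) nn_conv(C, C, k = 3L, dilation = 2L)
           else nn_cnr(C, C, k = 3L, dilation = 2L)
  m <- list(kind = "ga", softmax = softmax,
            params = list(cr1 = cr1$params, cr2 = cr2$params,
                          ar1 = ar1$params, ar2 = ar2$params,
                          fuse1 = fuse1$params, fuse2 = fuse2$params))
  m$forward <- function(x) {
    fcr <- cr2$forward(cr1$forward(x))
    far <- ar2$forward(ar1$forward(x))
    fga <- ag_concat_c(list(fcr, far))
    out <- fuse2$forward(fuse1$forward(fga))
    if (softmax) out <- ag_spatial_softmax_mc(out)
    out
  }
  m
}

#' Scale attention module
#'
#' Four steps: (1) channel-group average and max pooling (`groups` outputs
#' each) concatenated into `Fs`; (2) adaptive average/max pooling of `Fs` to
#' 3x3, a shared 3x3 convolution and two shared fully connected layers
#' (squeeze ratio 4) produce the excitation vectors FSE1 and FSE2; (3) their
#' sum rescales `Fs` channel-wise and a `k` x `k` convolution reduces it to a
#' one-channel logit map; (4) a spatial softmax turns the logits into weights
#' summing to 1 over H x W, which multiply the input across channels.
#'
#' @param channels input channel count C (must be >= `groups`)
#' @param groups pooled channel count per pooling branch (ablation grid:
#'   1/4/8/16; default 8)
#' @param k kernel size of the convolution producing the spatial logits
#'   (ablation grid: 1 or 7; default 1)
#' @param use_se include the squeeze-and-excitation pair (FALSE reproduces
#'   the "w/o SE" ablation)
#' @param rescale_by_hw multiply softmax weights by H*W to preserve feature
#'   magnitude (off by default: weights sum to one, faithful to the spatial
#'   softmax definition)
#' @return module list with `$forward` and `$params`
#' @export
nn_sa <- function(channels, groups = 8L, k = 1L, use_se = TRUE,
                  rescale_by_hw = FALSE) {
  C <- channels
  if (C < groups) stop("scale attention needs C >= ", groups, " channels")
  pooled <- 2L * groups
  se_conv <- nn_conv(pooled, pooled, k = 3L)   # shared between the two branches
  nflat <- pooled * 9L
  fc_sq <- nn_linear(nflat, max(4L, nflat %/% 4L))
  fc_ex <- nn_linear(max(4L, nflat %/% 4L), pooled)
  logit_conv <- nn_conv(pooled, 1L, k = as.integer(k))
  m <- list(kind = "sa", groups = groups, use_se = use_se,
            rescale_by_hw = rescale_by_hw,
            params = list(se_conv = se_conv$params, fc_sq = fc_sq$params,
                          fc_ex = fc_ex$params, logit_conv = logit_conv$params))
  se_branch <- function(pool3) {
    z <- ag_relu(se_conv$forward(pool3))
    z <- ag_reshape(z, length(z$val))
    fc_ex$forward(ag_relu(fc_sq$forward(z)))
  }
  m$forward <- function(x) {
    fs <- ag_concat_c(list(ag_chan_group_pool(x, groups, "avg"),
                           ag_chan_group_pool(x, groups, "max")))
    if (use_se) {
      fse1 <- se_branch(ag_adaptive_pool(fs, c(3L, 3L), "avg"))
      fse2 <- se_branch(ag_adaptive_pool(fs, c(3L, 3L), "max"))
      fs <- ag_mul_channel(fs, ag_add(fse1, fse2))
    }
    fsa <- logit_conv$forward(fs)
    w <- ag_spatial_softmax(fsa)
    if (rescale_by_hw) {
      d <- dim(x$val)
      w <- ag_scale(w, d[1] * d[2])
    }
    ag_mul_spatial(x, w)
  }
  # expose intermediates for inspection/tests
  m$intermediates <- function(x) {
    x <- as_ag(x)
    fs <- ag_concat_c(list(ag_chan_group_pool(x, groups, "avg"),
                           ag_chan_group_pool(x, groups, "max")))
    fse1 <- if (use_se) se_branch(ag_adaptive_pool(fs, c(3L, 3L), "avg")) else NULL
    fse2 <- if (use_se) se_branch(ag_adaptive_pool(fs, c(3L, 3L), "max")) else NULL
    fsw <- if (use_se) ag_mul_channel(fs, ag_add(fse1, fse2)) else fs
    fsa <- logit_conv$forward(fsw)
    w <- ag_spatial_softmax(fsa)
    list(Fs = fs$val, FSE1 = if (use_se) fse1$val, FSE2 = if (use_se) fse2$val,
         Fsa = fsa$val, weights = w$val)
  }
  m
}

#' Attention block factory: none / GA / SA / their fusions
#'
#' `variant = "ga_sa"` is coarse-to-fine attention (CTFA): GA, a point-wise
#' smoothing convolution, then SA. `"sa_ga"` reverses the order, `"parallel"`
#' runs GA and SA side by side and fuses by concatenation + point-wise
#' convolution (+norm/ReLU), `"sa_sa"` stacks two independent SA blocks, and
#' `"none"` is the identity (plain detector baseline).
#'
#' @param channels channel count of the attended feature map
#' @param variant one of "ga_sa", "sa_ga", "parallel", "ga", "sa", "sa_sa",
#'   "none"
#' @param ga_softmax,sa_groups,sa_k,sa_use_se,sa_rescale_by_hw forwarded to
#'   [nn_ga()] / [nn_sa()]
#' @return module list with `$forward` and `$params`
#' @export
nn_attention <- function(channels, variant = c("ga_sa", "sa_ga", "parallel",
                                               "ga", "sa", "sa_sa", "none"),
                         ga_softmax = FALSE, sa_groups = 8L, sa_k = 1L,
                         sa_use_se = TRUE, sa_rescale_by_hw = FALSE) {
  variant <- match.arg(variant)
  C <- channels
  mk_ga <- function() nn_ga(C, softmax = ga_softmax)
  mk_sa <- function() nn_sa(C, groups = sa_groups, k = sa_k,
                            use_se = sa_use_se,
                            rescale_by_hw = sa_rescale_by_hw)
  if (variant == "none") {
    return(list(kind = "attention", variant = variant, params = list(),
                forward = function(x) as_ag(x)))
  }
  mods <- switch(variant,
    ga = list(ga = mk_ga()),
    sa = list(sa = mk_sa()),
    sa_sa = list(sa1 = mk_sa(), sa2 = mk_sa()),
    ga_sa = list(ga = mk_ga(), smooth = nn_cnr(C, C, k = 1L), sa = mk_sa()),
    sa_ga = list(sa = mk_sa(), smooth = nn_cnr(C, C, k = 1L), ga = mk_ga()),
    parallel = list(ga = mk_ga(), sa = mk_sa(),
                    fuse = nn_cnr(2L * C, C, k = 1L)))
  fwd <- switch(variant,
    ga = function(x) mods$ga$forward(as_ag(x)),
    sa = function(x) mods$sa$forward(as_ag(x)),
    sa_sa = function(x) mods$sa2$forward(mods$sa1$forward(as_ag(x))),
    ga_sa = function(x) mods$sa$forward(mods$smooth$forward(mods$ga$forward(as_ag(x)))),
    sa_ga = function(x) mods$ga$forward(mods$smooth$forward(mods$sa$forward(as_ag(x)))),
    parallel = function(x) {
      x <- as_ag(x)
      mods$fuse$forward(ag_concat_c(list(mods$ga$forward(x), mods$sa$forward(x))))
    })
  list(kind = "attention", variant = variant,
       params = lapply(mods, `[[`, "params"), mods = mods, forward = fwd)
}

#' Apply an attention module to a plain (H, W, C) array
#' @param module a module from [nn_ga()], [nn_sa()] or [nn_attention()]
#' @param x numeric (H, W, C) array
#' @return numeric (H, W, C) array
#' @export
attention_apply <- function(module, x) {
  module$forward(ag_const(x))$val
}
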