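# Detector assembly: residual backbone with the last down-sampling removed,
# coarse-to-fine attention on the channel-reduced C5, FPN neck (P2-P7), a
# shared anchor-free detection head (classification, box-distance regression
# and centerness per location), and a pyramid-fused segmentation branch.
#
# Strides: the stage-5 down-sampling is replaced by dilation 2, so C5 keeps
# stride 16; the pyramid runs P2/4, P3/8, P4/16, P5/16, P6/32, P7/64.

#' Detector configuration
#'
#' `profile = "full"` mirrors the clinical-scale architecture (ResNet50-width
#' backbone, 256-channel neck, 4-conv head towers, shorter-side-800 inputs).
#' `profile = "desk"` is a width-reduced configuration of the same topology
#' sized for CPU-scale training on small synthetic images.
#'
#' @param profile "full" or "desk"
#' @param ... named overrides of any config field
#' @return list of class `detector_config`
#' @export
detector_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    n_classes = 4L,
    attention = "ga_sa",
    ga_softmax = FALSE,
    sa_groups = 8L, sa_k = 1L, sa_use_se = TRUE, sa_rescale_by_hw = FALSE,
    seg_classes = c("ETT", "tracheal_bifurcation"),
    seg_fusion = TRUE,
    freeze_backbone_norm = TRUE,
    norm_groups = 8L,
    strides = c(P3 = 8L, P4 = 16L, P5 = 16L, P6 = 32L, P7 = 64L),
    score_thresh = 0.05,
    nms_iou = 0.6,
    focal_alpha = 0.25, focal_gamma = 2,
    seg_lambda = 1)
  if (profile == "full") {
    base <- c(base, list(
      stem_ch = 64L, stage_ch = c(256L, 512L, 1024L, 2048L),
      stage_blocks = c(3L, 4L, 6L, 3L),
      neck_ch = 256L, head_convs = 4L, seg_convs = 4L,
      level_ranges = rbind(c(0, 64), c(64, 128), c(128, 256),
                           c(256, 512), c(512, Inf))))
  } else {
    base <- c(base, list(
      stem_ch = 8L, stage_ch = c(8L, 16L, 32L, 64L),
      stage_blocks = c(1L, 1L, 1L, 1L),
      neck_ch = 16L, head_convs = 1L, seg_convs = 4L,
      level_ranges = rbind(c(0, 32), c(32, 64), c(64, 128),
                           c(128, 256), c(256, Inf))))
  }
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  structure(base, class = "detector_config")
}

# bottleneck residual block (expansion 4)
nn_bottleneck <- function(in_ch, out_ch, stride = 1L, dilation = 1L,
                          norm_groups = 8L, frozen_norm = FALSE) {
  mid <- max(4L, out_ch %/% 4L)
  c1 <- nn_cnr(in_ch, mid, k = 1L, norm_groups = norm_groups,
               frozen_norm = frozen_norm)
  c2 <- nn_cnr(mid, mid, k = 3L, stride = stride, dilation = dilation,
               norm_groups = norm_groups, frozen_norm = frozen_norm)
  c3 <- nn_cnr(mid, out_ch, k = 1L, norm_groups = norm_groups,
               frozen_norm = frozen_norm, relu = FALSE)
  proj <- if (in_ch != out_ch || stride != 1L)
    nn_cnr(in_ch, out_ch, k = 1L, stride = stride,
           norm_groups = norm_groups, frozen_norm = frozen_norm, relu = FALSE)
  else NULL
  params <- list(c1 = c1$params, c2 = c2$params, c3 = c3$params)
  if (!is.null(proj)) params$proj <- proj$params
  m <- list(kind = "bottleneck", params = params)
  m$forward <- function(x) {
    y <- c3$forward(c2$forward(c1$forward(x)))
    sc <- if (is.null(proj)) x else proj$forward(x)
    ag_relu(ag_add(y, sc))
  }
  m
}

nn_res_stage <- function(in_ch, out_ch, n_blocks, stride, dilation = 1L,
                         norm_groups = 8L, frozen_norm = FALSE) {
  blocks <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    blocks[[i]] <- nn_bottleneck(if (i == 1L) in_ch else out_ch, out_ch,
                                 stride = if (i == 1L) stride else 1L,
                                 dilation = dilation,
                                 norm_groups = norm_groups,
                                 frozen_norm = frozen_norm)
  }
  m <- list(kind = "stage", params = lapply(blocks, `[[`, "params"))
  m$forward <- function(x) {
    for (b in blocks) x <- b$forward(x)
    x
  }
  m
}

#' Build the full detector
#'
#' @param config a [detector_config()]
#' @return model list with `$forward(image_matrix)` (returns per-level head
#'   outputs, the segmentation logits and the pyramid), `$params` (flat named
#'   parameter list), `$config`
#' @export
build_model <- function(config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  ng <- config$norm_groups
  fz <- config$freeze_backbone_norm
  nc <- config$neck_ch

  stem_conv <- nn_cnr(1L, config$stem_ch, k = 7L, stride = 2L,
                      norm_groups = ng, frozen_norm = fz)
  st <- config$stage_ch
  s2 <- nn_res_stage(config$stem_ch, st[1], config$stage_blocks[1], 1L,
                     norm_groups = ng, frozen_norm = fz)
  s3 <- nn_res_stage(st[1], st[2], config$stage_blocks[2], 2L,
                     norm_groups = ng, frozen_norm = fz)
  s4 <- nn_res_stage(st[2], st[3], config$stage_blocks[3], 2L,
                     norm_groups = ng, frozen_norm = fz)
  # last down-sampling removed: stride 1 with dilation 2 keeps C5 at /16
  s5 <- nn_res_stage(st[3], st[4], config$stage_blocks[4], 1L, dilation = 2L,
                     norm_groups = ng, frozen_norm = fz)

  c5_reduce <- nn_conv(st[4], nc, k = 1L)
  attn <- nn_attention(nc, variant = config$attention,
                       ga_softmax = config$ga_softmax,
                       sa_groups = config$sa_groups, sa_k = config$sa_k,
                       sa_use_se = config$sa_use_se,
                       sa_rescale_by_hw = config$sa_rescale_by_hw)

  lat2 <- nn_conv(st[1], nc, k = 1L)
  lat3 <- nn_conv(st[2], nc, k = 1L)
  lat4 <- nn_conv(st[3], nc, k = 1L)
  out2 <- nn_conv(nc, nc, k = 3L)
  out3 <- nn_conv(nc, nc, k = 3L)
  out4 <- nn_conv(nc, nc, k = 3L)
  out5 <- nn_conv(nc, nc, k = 3L)
  p6_conv <- nn_conv(nc, nc, k = 3L, stride = 2L)
  p7_conv <- nn_conv(nc, nc, k = 3L, stride = 2L)

  mk_tower <- function(n) {
    mods <- lapply(seq_len(n), function(i)
      nn_cnr(nc, nc, k = 3L, norm_groups = ng))
    do.call(nn_sequential, mods)
  }
  cls_tower <- mk_tower(config$head_convs)
  reg_tower <- mk_tower(config$head_convs)
  # focal-style prior keeps early classification scores near 0.01
  cls_head <- nn_conv(nc, config$n_classes, k = 3L,
                      bias_init = -log((1 - 0.01) / 0.01))
  reg_head <- nn_conv(nc, 4L, k = 3L)
  ctr_head <- nn_conv(nc, 1L, k = 3L)
  level_scales <- lapply(seq_len(5L), function(i) ag_param(1))

  n_seg_cls <- length(config$seg_classes) + 1L  # + background
  seg_trunk <- do.call(nn_sequential, lapply(seq_len(config$seg_convs),
    function(i) nn_cnr(nc, nc, k = 3L, norm_groups = ng)))
  seg_head <- nn_conv(nc, n_seg_cls, k = 3L)

  modules <- list(stem = stem_conv, s2 = s2, s3 = s3, s4 = s4, s5 = s5,
                  c5_reduce = c5_reduce, attn = attn,
                  lat2 = lat2, lat3 = lat3, lat4 = lat4,
                  out2 = out2, out3 = out3, out4 = out4, out5 = out5,
                  p6 = p6_conv, p7 = p7_conv,
                  cls_tower = cls_tower, reg_tower = reg_tower,
                  cls_head = cls_head, reg_head = reg_head,
                  ctr_head = ctr_head,
                  seg_trunk = seg_trunk, seg_head = seg_head)
  ptree <- c(lapply(modules, `[[`, "params"),
             list(level_scales = level_scales))
  params <- collect_params(ptree)

  strides <- config$strides

  forward <- function(image, with_seg = TRUE) {
    if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
    x <- ag_const((image - 0.5) / 0.25)
    x <- stem_conv$forward(x)
    x <- ag_maxpool(x, 3L, 2L, 1L)
    c2 <- s2$forward(x)
    c3 <- s3$forward(c2)
    c4 <- s4$forward(c3)
    c5 <- s5$forward(c4)

    t5 <- attn$forward(c5_reduce$forward(c5))
    # top-down pathway; C4 and C5 share stride 16 so no upsampling there
    m4 <- ag_add(lat4$forward(c4), ag_crop_pad(t5, dim(c4$val)[1], dim(c4$val)[2]))
    u4 <- ag_upsample_nearest(m4, 2L)
    m3 <- ag_add(lat3$forward(c3), ag_crop_pad(u4, dim(c3$val)[1], dim(c3$val)[2]))
    u3 <- ag_upsample_nearest(m3, 2L)
    m2 <- ag_add(lat2$forward(c2), ag_crop_pad(u3, dim(c2$val)[1], dim(c2$val)[2]))
    p2 <- out2$forward(m2)
    p3 <- out3$forward(m3)
    p4 <- out4$forward(m4)
    p5 <- out5$forward(t5)
    p6 <- p6_conv$forward(p5)
    p7 <- p7_conv$forward(ag_relu(p6))
    plev <- list(P3 = p3, P4 = p4, P5 = p5, P6 = p6, P7 = p7)

    levels <- lapply(seq_along(plev), function(i) {
      p <- plev[[i]]
      ct <- cls_tower$forward(p)
      rt <- reg_tower$forward(p)
      cls <- cls_head$forward(ct)
      raw <- reg_head$forward(rt)
      ctr <- ctr_head$forward(rt)
      dist <- ag_scale(ag_exp(ag_mul(raw, level_scales[[i]])), strides[i])
      list(cls = cls, reg = dist, ctr = ctr, stride = strides[[i]])
    })
    names(levels) <- names(plev)

    seg <- NULL
    if (with_seg) {
      h2 <- dim(p2$val)[1]; w2 <- dim(p2$val)[2]
      fseg <- if (isTRUE(config$seg_fusion)) {
        acc <- p2
        for (pp in list(p3, p4, p5)) {
          f <- max(1L, round(h2 / dim(pp$val)[1]))
          acc <- ag_add(acc, ag_crop_pad(ag_upsample_nearest(pp, f), h2, w2))
        }
        acc
      } else p2
      seg <- seg_head$forward(ag_upsample_nearest(seg_trunk$forward(fseg), 4L))
    }
    list(levels = levels, seg = seg, pyramid = c(list(P2 = p2), plev))
  }

  list(config = config, modules = modules, params = params,
       level_scales = level_scales, forward = forward)
}

#' Count trainable parameters of a model
#' @param model from [build_model()]
#' @return integer parameter count
#' @export
count_parameters <- function(model) {
  n_trainable(model$params)
}

#' Estimate forward multiply-accumulate FLOPs at a given input size
#'
#' Counts convolution and fully connected multiply-accumulates for one
#' forward pass (the standard accounting for detector complexity tables).
#' @param model from [build_model()]
#' @param input_size image side in pixels (default 224)
#' @return numeric MAC count
#' @export
count_flops <- function(model, input_size = 224L) {
  .ag_env$flops <- 0
  on.exit(.ag_env$flops <- NULL)
  img <- matrix(0.5, input_size, input_size)
  invisible(model$forward(img))
  .ag_env$flops
}

#' Save / load a model checkpoint (weights + config)
#' @param model from [build_model()]
#' @param path checkpoint file
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               state = params_state(model$params),
               param_names = names(model$params)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return for `load_checkpoint`, a rebuilt model with restored weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  config <- structure(ck$config, class = "detector_config")
  model <- build_model(config)
  if (!identical(names(model$params), ck$param_names))
    stop("checkpoint/config mismatch: parameter sets differ")
  params_restore(model$params, ck$state)
  model
}
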