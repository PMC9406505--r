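# Structured ops on (H, W, C) feature maps for the autodiff engine.

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L, dilation = 1L) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  out <- .conv2d_fwd(x$val, w$val, b$val, as.integer(stride), as.integer(pad),
                     as.integer(dilation))
  if (!is.null(.ag_env$flops)) {
    d <- dim(out); wd <- dim(w$val)
    .ag_env$flops <- .ag_env$flops +
      as.numeric(wd[1]) * wd[2] * wd[3] * wd[4] * d[1] * d[2]
  }
  ag_node(out, list(x, w, b), function(g) {
    gr <- .conv2d_bwd(x$val, w$val, g, as.integer(stride), as.integer(pad),
                      as.integer(dilation))
    list(gr$gx, gr$gw, gr$gb)
  })
}

ag_maxpool <- function(x, k = 2L, stride = 2L, pad = 0L) {
  x <- as_ag(x)
  fw <- .maxpool2d_fwd(x$val, as.integer(k), as.integer(stride), as.integer(pad))
  xdim <- dim(x$val)
  ag_node(fw$out, list(x), function(g)
    list(.maxpool2d_bwd(g, fw$argmax, as.integer(xdim))))
}

#' Group normalization over spatial x channel-group extents of one sample.
#'
#' `groups = C` gives instance norm (the per-sample realization of a
#' batch-norm slot); `groups = 1` gives layer norm. Population variance.
#' @noRd
ag_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(C %% groups == 0L)
  cg <- C %/% groups
  m <- H * W * cg                       # elements per group
  xv <- x$val
  dim(xv) <- c(H * W * cg, groups)
  mu <- colMeans(xv)
  va <- colMeans(xv^2) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- (xv - rep(mu, each = H * W * cg)) * rep(istd, each = H * W * cg)
  dim(xhat) <- c(H, W, C)
  gam <- rep(gamma$val, each = H * W)   # per-channel affine
  bet <- rep(beta$val, each = H * W)
  out <- xhat * gam + bet
  dim(out) <- c(H, W, C)
  ag_node(out, list(x, gamma, beta), function(g) {
    gflat <- g
    dim(gflat) <- c(H * W, C)
    xh <- xhat
    dim(xh) <- c(H * W, C)
    ggamma <- colSums(gflat * xh)
    gbeta <- colSums(gflat)
    dxhat <- g * gam
    dim(dxhat) <- c(H * W * cg, groups)
    xh2 <- xhat
    dim(xh2) <- c(H * W * cg, groups)
    mean_d <- colMeans(dxhat)
    mean_dx <- colMeans(dxhat * xh2)
    gx <- (dxhat - rep(mean_d, each = m) - xh2 * rep(mean_dx, each = m)) *
      rep(istd, each = m)
    dim(gx) <- c(H, W, C)
    list(gx, ggamma, gbeta)
  })
}

# fully connected: x vector (n), W (n_out x n_in), b (n_out)
ag_linear <- function(x, w, b) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  xv <- as.numeric(x$val)
  out <- as.numeric(w$val %*% xv) + b$val
  if (!is.null(.ag_env$flops)) .ag_env$flops <- .ag_env$flops + length(w$val)
  ag_node(out, list(x, w, b), function(g) {
    g <- as.numeric(g)
    list(as.numeric(crossprod(w$val, g)), outer(g, xv), g)
  })
}

ag_concat_c <- function(xs) {
  xs <- lapply(xs, as_ag)
  ds <- lapply(xs, function(x) dim(x$val))
  H <- ds[[1]][1]; W <- ds[[1]][2]
  cs <- vapply(ds, `[`, integer(1), 3L)
  out <- array(0, dim = c(H, W, sum(cs)))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, , off + seq_len(cs[i])] <- xs[[i]]$val
    off <- off + cs[i]
  }
  ag_node(out, xs, function(g) {
    off <- 0L
    lapply(seq_along(xs), function(i) {
      gi <- g[, , off + seq_len(cs[i]), drop = FALSE]
      off <<- off + cs[i]
      gi
    })
  })
}

#' Channel-group pooling: (H,W,C) -> (H,W,groups) by mean or max over
#' contiguous channel groups; a non-divisible remainder goes to the last group.
#' @noRd
ag_chan_group_pool <- function(x, groups = 8L, type = c("avg", "max")) {
  type <- match.arg(type)
  x <- as_ag(x)
  d <- dim(x$val); H <- d[1]; W <- d[2]; C <- d[3]
  if (C < groups) stop("channel-group pooling needs C >= groups (C=", C, ")")
  base <- C %/% groups
  sizes <- rep(base, groups)
  sizes[groups] <- sizes[groups] + C - base * groups
  starts <- cumsum(c(0L, sizes[-groups]))
  out <- array(0, dim = c(H, W, groups))
  argmax <- if (type == "max") array(0L, dim = c(H, W, groups)) else NULL
  for (gidx in seq_len(groups)) {
    sl <- x$val[, , starts[gidx] + seq_len(sizes[gidx]), drop = FALSE]
    if (type == "avg") {
      out[, , gidx] <- apply(sl, c(1, 2), mean)
    } else {
      dim(sl) <- c(H * W, sizes[gidx])
      am <- max.col(sl, ties.method = "first")
      out[, , gidx] <- sl[cbind(seq_len(H * W), am)]
      argmax[, , gidx] <- am
    }
  }
  ag_node(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (gidx in seq_len(groups)) {
      ch <- starts[gidx] + seq_len(sizes[gidx])
      if (type == "avg") {
        gx[, , ch] <- gx[, , ch] + array(g[, , gidx] / sizes[gidx],
                                         dim = c(H, W, sizes[gidx]))
      } else {
        gsl <- array(0, dim = c(H * W, sizes[gidx]))
        am <- as.integer(argmax[, , gidx])
        gsl[cbind(seq_len(H * W), am)] <- as.numeric(g[, , gidx])
        dim(gsl) <- c(H, W, sizes[gidx])
        gx[, , ch] <- gx[, , ch] + gsl
      }
    }
    list(gx)
  })
}

# adaptive pooling to an (oh x ow) grid, torch-style bin edges
adaptive_bins <- function(n, o) {
  lo <- floor((seq_len(o) - 1L) * n / o) + 1L
  hi <- ceiling(seq_len(o) * n / o)
  cbind(lo, hi)
}

ag_adaptive_pool <- function(x, out_hw = c(3L, 3L), type = c("avg", "max")) {
  type <- match.arg(type)
  x <- as_ag(x)
  d <- dim(x$val); H <- d[1]; W <- d[2]; C <- d[3]
  oh <- out_hw[1]; ow <- out_hw[2]
  hb <- adaptive_bins(H, oh); wb <- adaptive_bins(W, ow)
  out <- array(0, dim = c(oh, ow, C))
  arg <- if (type == "max") array(0L, dim = c(oh, ow, C, 2L)) else NULL
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sl <- x$val[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], , drop = FALSE]
    if (type == "avg") {
      out[i, j, ] <- apply(sl, 3, mean)
    } else {
      for (c in seq_len(C)) {
        m <- which.max(sl[, , c])
        nh <- hb[i, 2] - hb[i, 1] + 1L
        out[i, j, c] <- sl[, , c][m]
        arg[i, j, c, ] <- c(hb[i, 1] + (m - 1L) %% nh,
                            wb[j, 1] + (m - 1L) %/% nh)
      }
    }
  }
  ag_node(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      if (type == "avg") {
        nh <- hb[i, 2] - hb[i, 1] + 1L
        nw <- wb[j, 2] - wb[j, 1] + 1L
        per <- array(rep(g[i, j, ] / (nh * nw), each = nh * nw), dim = c(nh, nw, C))
        gx[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], ] <-
          gx[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], ] + per
      } else {
        for (c in seq_len(C)) {
          gx[arg[i, j, c, 1], arg[i, j, c, 2], c] <-
            gx[arg[i, j, c, 1], arg[i, j, c, 2], c] + g[i, j, c]
        }
      }
    }
    list(gx)
  })
}

# nearest-neighbour upsampling by an integer factor
ag_upsample_nearest <- function(x, factor) {
  x <- as_ag(x)
  d <- dim(x$val); H <- d[1]; W <- d[2]; C <- d[3]
  f <- as.integer(factor)
  if (f == 1L) return(x)
  hi <- rep(seq_len(H), each = f)
  wi <- rep(seq_len(W), each = f)
  out <- x$val[hi, wi, , drop = FALSE]
  ag_node(out, list(x), function(g) {
    # sum the f x f block of output grads feeding each input cell
    gh <- rowsum(matrix(g, nrow = H * f), group = rep(seq_len(H), each = f))
    dim(gh) <- c(H, W * f, C)
    gw <- rowsum(matrix(aperm(gh, c(2, 1, 3)), nrow = W * f),
                 group = rep(seq_len(W), each = f))
    dim(gw) <- c(W, H, C)
    list(aperm(gw, c(2, 1, 3)))
  })
}

# crop or zero-pad (bottom/right) to an exact (H, W); used to absorb the
# <=1 px size drift of repeated down/up-sampling on odd extents
ag_crop_pad <- function(x, H, W) {
  x <- as_ag(x)
  d <- dim(x$val)
  if (d[1] == H && d[2] == W) return(x)
  C <- d[3]
  out <- array(0, dim = c(H, W, C))
  hh <- min(H, d[1]); ww <- min(W, d[2])
  out[seq_len(hh), seq_len(ww), ] <- x$val[seq_len(hh), seq_len(ww), , drop = FALSE]
  ag_node(out, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[seq_len(hh), seq_len(ww), ] <- g[seq_len(hh), seq_len(ww), , drop = FALSE]
    list(gx)
  })
}

# softmax over all H*W positions of a single-channel map; weights sum to 1
ag_spatial_softmax <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  stopifnot(d[3] == 1L)
  v <- as.numeric(x$val)
  e <- exp(v - max(v))
  s <- e / sum(e)
  out <- array(s, dim = d)
  ag_node(out, list(x), function(g) {
    g <- as.numeric(g)
    gx <- s * (g - sum(g * s))
    list(array(gx, dim = d))
  })
}

# softmax over the H*W positions of every channel independently
ag_spatial_softmax_mc <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val); H <- d[1]; W <- d[2]; C <- d[3]
  m <- matrix(x$val, nrow = H * W)
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  p <- sweep(e, 2, colSums(e), "/")
  out <- array(p, dim = d)
  ag_node(out, list(x), function(g) {
    gm <- matrix(g, nrow = H * W)
    dot <- colSums(gm * p)
    gx <- p * sweep(gm, 2, dot)
    list(array(gx, dim = d))
  })
}

# per-pixel softmax over the channel axis
ag_softmax_c <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val); H <- d[1]; W <- d[2]; C <- d[3]
  m <- matrix(x$val, nrow = H * W)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  out <- array(p, dim = d)
  ag_node(out, list(x), function(g) {
    gm <- matrix(g, nrow = H * W)
    dot <- rowSums(gm * p)
    gx <- p * (gm - dot)
    list(array(gx, dim = d))
  })
}

# (H,W,C) * (H,W,1): the same spatial weight applied to every channel
ag_mul_spatial <- function(x, w1) {
  x <- as_ag(x); w1 <- as_ag(w1)
  d <- dim(x$val); C <- d[3]
  wmap <- array(w1$val, dim = c(d[1], d[2]))
  out <- x$val * as.numeric(wmap)
  ag_node(out, list(x, w1), function(g) {
    gw <- apply(g * x$val, c(1, 2), sum)
    dim(gw) <- c(d[1], d[2], 1L)
    list(g * as.numeric(wmap), gw)
  })
}

# (H,W,C) * per-channel vector (length C)
ag_mul_channel <- function(x, vc) {
  x <- as_ag(x); vc <- as_ag(vc)
  d <- dim(x$val)
  scale <- rep(as.numeric(vc$val), each = d[1] * d[2])
  out <- x$val * scale
  ag_node(out, list(x, vc), function(g) {
    gv <- colSums(matrix(g * x$val, nrow = d[1] * d[2]))
    list(g * scale, gv)
  })
}
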