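# Reverse-mode autodiff on dense R arrays.
#
# A node is an environment holding a value, its parents, and a backward
# closure mapping the output gradient to one gradient per parent. The graph
# is define-by-run: every op builds a node and the tape is recovered by a
# depth-first topological sort at backward time. Values are plain R arrays
# (feature maps use dim (H, W, C)); the heavy kernels live in src/.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

ag_next_id <- function() {
  .ag_env$counter <- .ag_env$counter + 1L
  .ag_env$counter
}

#' @noRd
ag_node <- function(val, parents = list(), backward = NULL, requires_grad = TRUE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$requires_grad <- requires_grad || length(parents) > 0L
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

ag_const <- function(val) ag_node(val, requires_grad = FALSE)

ag_param <- function(val) {
  e <- ag_node(val, requires_grad = TRUE)
  e$is_param <- TRUE
  e
}

is_ag <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

ag_value <- function(x) if (is_ag(x)) x$val else x

#' Run backpropagation from a scalar loss node
#'
#' Accumulates `$grad` on every reachable node that requires a gradient.
#' @noRd
ag_backward <- function(root) {
  stopifnot(is_ag(root), length(root$val) == 1L)
  # iterative DFS post-order
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$expanded) {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    } else if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, expanded = TRUE)
      for (p in nd$parents) {
        if (is_ag(p) && p$requires_grad && is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  order <- order[seq_len(n_ord)]
  root$grad <- array(1, dim = dim_or_len(root$val))
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!is_ag(p) || !p$requires_grad || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(root)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# zero gradients on a flat list of parameter nodes
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- elementwise primitives ------------------------------------------------

same_shape <- function(a, b) identical(dim_or_len(ag_value(a)), dim_or_len(ag_value(b)))

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$val; bv <- b$val
  scal_a <- length(av) == 1L; scal_b <- length(bv) == 1L
  if (!scal_a && !scal_b && !same_shape(a, b)) stop("ag_add: shape mismatch")
  ag_node(av + bv, list(a, b), function(g) list(
    if (scal_a && length(g) > 1L) sum(g) else g,
    if (scal_b && length(g) > 1L) sum(g) else g))
}

ag_sub <- function(a, b) ag_add(a, ag_scale(b, -1))

ag_scale <- function(a, k) {
  a <- as_ag(a)
  ag_node(a$val * k, list(a), function(g) list(g * k))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$val; bv <- b$val
  scal_a <- length(av) == 1L; scal_b <- length(bv) == 1L
  if (!scal_a && !scal_b && !same_shape(a, b)) stop("ag_mul: shape mismatch")
  ag_node(av * bv, list(a, b), function(g) list(
    { ga <- g * bv; if (scal_a && length(ga) > 1L) sum(ga) else ga },
    { gb <- g * av; if (scal_b && length(gb) > 1L) sum(gb) else gb }))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$val; bv <- b$val
  scal_a <- length(av) == 1L; scal_b <- length(bv) == 1L
  if (!scal_a && !scal_b && !same_shape(a, b)) stop("ag_div: shape mismatch")
  out <- av / bv
  ag_node(out, list(a, b), function(g) list(
    { ga <- g / bv; if (scal_a && length(ga) > 1L) sum(ga) else ga },
    { gb <- -g * av / (bv * bv); if (scal_b && length(gb) > 1L) sum(gb) else gb }))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  mask <- a$val > 0
  ag_node(a$val * mask, list(a), function(g) list(g * mask))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  s <- 1 / (1 + exp(-a$val))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_exp <- function(a) {
  a <- as_ag(a)
  e <- exp(a$val)
  ag_node(e, list(a), function(g) list(g * e))
}

ag_log <- function(a) {
  a <- as_ag(a)
  ag_node(log(a$val), list(a), function(g) list(g / a$val))
}

ag_sqrt <- function(a) {
  a <- as_ag(a)
  s <- sqrt(a$val)
  ag_node(s, list(a), function(g) list(g / (2 * s)))
}

ag_pow <- function(a, p) {
  a <- as_ag(a)
  ag_node(a$val^p, list(a), function(g) list(g * p * a$val^(p - 1)))
}

# numerically stable log(1 + exp(x)); derivative sigmoid(x)
ag_softplus <- function(a) {
  a <- as_ag(a)
  v <- a$val
  out <- ifelse(v > 0, v + log1p(exp(-v)), log1p(exp(v)))
  ag_node(out, list(a), function(g) list(g / (1 + exp(-v))))
}

# elementwise max/min; ties send the gradient to the first argument
ag_pmax <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$val; bv <- b$val
  take_a <- av >= bv
  ag_node(pmax(av, bv), list(a, b), function(g) {
    ga <- g * take_a; gb <- g * !take_a
    list(if (length(av) == 1L && length(g) > 1L) sum(ga) else ga,
         if (length(bv) == 1L && length(g) > 1L) sum(gb) else gb)
  })
}

ag_pmin <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$val; bv <- b$val
  take_a <- av <= bv
  ag_node(pmin(av, bv), list(a, b), function(g) {
    ga <- g * take_a; gb <- g * !take_a
    list(if (length(av) == 1L && length(g) > 1L) sum(ga) else ga,
         if (length(bv) == 1L && length(g) > 1L) sum(gb) else gb)
  })
}

ag_sum <- function(a) {
  a <- as_ag(a)
  d <- dim_or_len(a$val)
  ag_node(sum(a$val), list(a), function(g) list(array(as.numeric(g), dim = d)))
}

ag_mean <- function(a) {
  a <- as_ag(a)
  n <- length(a$val)
  d <- dim_or_len(a$val)
  ag_node(mean(a$val), list(a), function(g) list(array(as.numeric(g) / n, dim = d)))
}

ag_reshape <- function(a, dims) {
  a <- as_ag(a)
  old <- dim_or_len(a$val)
  v <- a$val
  dim(v) <- dims
  ag_node(v, list(a), function(g) { dim(g) <- old; list(g) })
}

# concatenate 1-D nodes into one vector
ag_cat_vec <- function(xs) {
  xs <- lapply(xs, as_ag)
  lens <- vapply(xs, function(x) length(x$val), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(unlist(lapply(xs, function(x) as.numeric(x$val))), xs, function(g) {
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i]])
  })
}

# gather scalar entries by flat (1-based) index; backward scatter-adds
ag_gather <- function(a, idx) {
  a <- as_ag(a)
  d <- dim_or_len(a$val)
  ag_node(as.numeric(a$val[idx]), list(a), function(g) {
    gx <- array(0, dim = d)
    # accumulate for repeated indices
    acc <- rowsum(as.numeric(g), group = idx)
    gx[as.numeric(rownames(acc))] <- acc[, 1L]
    list(gx)
  })
}
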