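# Shared fixtures: tiny deterministic landmark sets, numeric gradients, and
# a brute-force pixel rasterization oracle for IoU/GIoU.

# a hand-built, integer-coordinate 13-landmark annotation on a 512 image:
# tube segment ending at (110, 400), bifurcation Y with apex (256, 300)
fixture_landmarks <- function() {
  pts <- rbind(
    c(100, 300), c(100, 400), c(120, 400), c(120, 300),   # P1-P4 (ETT)
    c(246, 250), c(240, 280), c(200, 340), c(240, 330),   # P5-P8
    c(256, 300),                                          # P9 (carina)
    c(272, 330), c(312, 340), c(272, 280), c(266, 250))   # P10-P13
  landmarks13(pts, image_size = c(512L, 512L))
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# pixel-count IoU / GIoU on an integer grid (oracle for the analytic forms)
raster_giou <- function(a, b, grid = 300L) {
  xs <- seq_len(grid) - 0.5
  inbox <- function(bx) outer(xs >= bx[2] & xs <= bx[4],
                              xs >= bx[1] & xs <= bx[3], `&`)
  A <- inbox(a); B <- inbox(b)
  inter <- sum(A & B); un <- sum(A | B)
  iou <- if (un > 0) inter / un else 0
  cbox <- c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
  Cm <- inbox(cbox)
  areaC <- sum(Cm)
  if (areaC == 0) return(list(iou = iou, giou = iou))
  list(iou = iou, giou = iou - (areaC - un) / areaC)
}

# minimal single-level head output with one confident detection of `class`
# at image-space location (cx, cy) with side distances d
single_detection_output <- function(cx, cy, d, class_idx = 2L, stride = 8L,
                                    H = 32L, W = 32L) {
  cls <- array(-20, dim = c(H, W, 4L))
  reg <- array(1, dim = c(H, W, 4L))
  ctr <- array(-20, dim = c(H, W, 1L))
  xi <- (cx - stride / 2) / stride + 1L
  yi <- (cy - stride / 2) / stride + 1L
  stopifnot(xi == round(xi), yi == round(yi))
  cls[yi, xi, class_idx] <- 20
  ctr[yi, xi, 1] <- 20
  reg[yi, xi, ] <- d
  list(list(cls = cls, reg = reg, ctr = ctr, stride = stride))
}
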