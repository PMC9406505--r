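# Synthetic portable-radiograph generator.
#
# Emulates the image statistics the detector relies on: a smooth dark tube
# curve entering from the top edge and ending at a tip, a brighter tracheal
# band ending in a Y-shaped dark bifurcation whose apex is the Carina,
# Gaussian noise, and bright linear occluders (wires/electrodes). The
# tip-Carina distance is drawn from a two-component mixture over the
# clinically suitable [20, 70] mm window and its complement, so both
# suitability classes are realized with known ground truth.

#' Synthetic radiograph configuration
#'
#' @param image_size image side in pixels (square images)
#' @param pixel_spacing physical pixel size in mm/px
#' @param suitable_frac mixture weight of the "suitable" class: with this
#'   probability the tip-Carina distance is drawn U\[20, 70\] mm, otherwise
#'   from U\[0, 20) (weight 2/7) or U(70, 120\] (weight 5/7, proportional to
#'   interval length)
#' @param fixed_distance_mm if non-NULL, every case uses exactly this
#'   tip-Carina distance instead of sampling
#' @param feature_box_size side of the tip/Carina feature boxes in px;
#'   default scales the native 300 px box by `image_size / 2500`
#' @param tube_width_px,tube_intensity tube half-profile width and darkening
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units)
#' @param n_occluders number of bright linear occluders drawn *after* the
#'   tube so some tips are partially hidden
#' @return list of class `synth_config`
#' @export
synth_config <- function(image_size = 512L, pixel_spacing = NULL,
                         suitable_frac = 0.5, fixed_distance_mm = NULL,
                         feature_box_size = NULL,
                         tube_width_px = NULL, tube_intensity = 0.35,
                         noise_sd = 0.03, n_occluders = 3L) {
  # constant 256 mm field of view: smaller rasters get coarser spacing, so
  # the full unsuitable distance range (up to 120 mm) stays representable
  if (is.null(pixel_spacing)) pixel_spacing <- 0.5 * 512 / image_size
  stopifnot(pixel_spacing > 0, suitable_frac >= 0, suitable_frac <= 1,
            image_size >= 64)
  if (is.null(feature_box_size)) feature_box_size <- 300 * image_size / 2500
  if (is.null(tube_width_px)) tube_width_px <- max(3, round(image_size / 100))
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing,
                 suitable_frac = suitable_frac,
                 fixed_distance_mm = fixed_distance_mm,
                 feature_box_size = feature_box_size,
                 tube_width_px = tube_width_px,
                 tube_intensity = tube_intensity,
                 noise_sd = noise_sd,
                 n_occluders = as.integer(n_occluders)),
            class = "synth_config")
}

# additive soft-edged thick segment ("capsule") on an intensity matrix
draw_capsule <- function(img, p1, p2, halfw, delta) {
  n <- nrow(img)
  x0 <- max(1L, floor(min(p1[1], p2[1]) - halfw - 1)) ; x1 <- min(ncol(img), ceiling(max(p1[1], p2[1]) + halfw + 2))
  y0 <- max(1L, floor(min(p1[2], p2[2]) - halfw - 1)) ; y1 <- min(n, ceiling(max(p1[2], p2[2]) + halfw + 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- (x0:x1) - 1   # 0-based pixel coords
  ys <- (y0:y1) - 1
  d <- p2 - p1
  len2 <- sum(d^2)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  if (len2 < 1e-12) {
    dist <- sqrt((X - p1[1])^2 + (Y - p1[2])^2)
  } else {
    t <- pmin(pmax(((X - p1[1]) * d[1] + (Y - p1[2]) * d[2]) / len2, 0), 1)
    dist <- sqrt((X - (p1[1] + t * d[1]))^2 + (Y - (p1[2] + t * d[2]))^2)
  }
  # soft edge over one pixel
  w <- pmin(pmax(halfw + 0.5 - dist, 0), 1)
  img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] + delta * w
  img
}

# quadratic bezier polyline
bezier_points <- function(p0, p1, p2, n = 40L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

sample_distance_mm <- function(config) {
  if (!is.null(config$fixed_distance_mm)) return(config$fixed_distance_mm)
  if (runif(1) < config$suitable_frac) {
    runif(1, 20, 70)
  } else if (runif(1) < 20 / 70) {
    runif(1, 0, 20 - 1e-9)
  } else {
    runif(1, 70 + 1e-9, 120)
  }
}

#' Generate one labelled synthetic radiograph
#'
#' @param config a [synth_config()]
#' @param seed integer seed; the case is bit-reproducible given
#'   (config, seed)
#' @return list of class `synth_case`: `$image` (H x W intensity matrix in
#'   \[0,1\]), `$landmarks` ([landmarks13()]), `$distance_mm`, `$label`
#'   ("suitable"/"unsuitable"), `$pixel_spacing`
#' @export
generate_case <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  s <- config$image_size
  sp <- config$pixel_spacing
  d_mm <- sample_distance_mm(config)
  d_px <- d_mm / sp
  if (d_px > 0.48 * s)
    stop("config error: tip-Carina distance ", round(d_mm, 1),
         " mm is infeasible for image size ", s, " at ", sp, " mm/px")

  # --- geometry -------------------------------------------------------------
  carina <- c(runif(1, 0.42, 0.58) * s, runif(1, 0.55, 0.65) * s)
  theta <- rnorm(1, 0, 4) * pi / 180       # tube direction off vertical
  up <- c(sin(theta), -cos(theta))
  tip <- carina + d_px * up
  halfw <- config$tube_width_px / 2
  nvec <- c(-up[2], up[1])                 # unit normal to the tube axis

  # ETT landmarks: P2/P3 straddle the tip so their midpoint is the tip
  seg_len <- 0.22 * s                      # labelled distal tube segment
  back <- tip - seg_len * up
  P2 <- tip - halfw * nvec
  P3 <- tip + halfw * nvec
  P1 <- back - halfw * nvec
  P4 <- back + halfw * nvec

  # bifurcation landmarks around the Y; apex is the Carina (P9)
  wt <- max(4, 0.02 * s)                   # tracheal half-width
  lt <- 0.10 * s                           # labelled tracheal stem above apex
  lb <- 0.12 * s                           # bronchial branch length
  angL <- (35 + rnorm(1, 0, 4)) * pi / 180
  angR <- (38 + rnorm(1, 0, 4)) * pi / 180
  dirL <- c(-sin(angL), cos(angL))
  dirR <- c(sin(angR), cos(angR))
  P5 <- carina + c(-wt, -lt)
  P6 <- carina + c(-wt * 1.4, -lt * 0.4)
  P7 <- carina + lb * dirL + wt * c(-dirL[2], dirL[1]) * -1
  P8 <- carina + lb * 0.55 * dirL + c(wt * 0.6, wt * 0.8)
  P9 <- carina
  P10 <- carina + lb * 0.55 * dirR + c(-wt * 0.6, wt * 0.8)
  P11 <- carina + lb * dirR + wt * c(dirR[2], -dirR[1]) * -1
  P12 <- carina + c(wt * 1.4, -lt * 0.4)
  P13 <- carina + c(wt, -lt)

  pts <- rbind(P1, P2, P3, P4, P5, P6, P7, P8, P9, P10, P11, P12, P13)
  pts[, 1] <- pmin(pmax(pts[, 1], 1), s - 2)
  pts[, 2] <- pmin(pmax(pts[, 2], 1), s - 2)
  # clamping must not move the geometry that defines the distance
  pts[2, ] <- P2; pts[3, ] <- P3; pts[9, ] <- P9

  # --- image ----------------------------------------------------------------
  xs <- seq(0, 1, length.out = s)
  img <- matrix(0.45, s, s)
  img <- img + outer(0.10 * xs, rep(1, s))              # vertical gradient
  # darker lung fields left/right of the mediastinum
  cx <- carina[1] / s
  lungL <- exp(-((outer(rep(1, s), xs) - (cx - 0.22))^2) / (2 * 0.012)) *
    exp(-((outer(xs, rep(1, s)) - 0.45)^2) / (2 * 0.05))
  lungR <- exp(-((outer(rep(1, s), xs) - (cx + 0.22))^2) / (2 * 0.012)) *
    exp(-((outer(xs, rep(1, s)) - 0.45)^2) / (2 * 0.05))
  img <- img - 0.12 * (lungL + lungR)

  # brighter tracheal band from the top of the image down to the carina
  trach_top <- carina - c(0, 0.35 * s)
  img <- draw_capsule(img, trach_top, carina, wt * 2.0, 0.10)
  # dark air column inside the trachea and the Y bronchi (apex = carina)
  img <- draw_capsule(img, trach_top, carina, wt * 0.8, -0.10)
  img <- draw_capsule(img, carina, carina + lb * dirL, wt * 0.8, -0.14)
  img <- draw_capsule(img, carina, carina + lb * dirR, wt * 0.8, -0.14)

  # the ETT: dark smooth curve from the top edge ending at the tip
  entry <- c(tip[1] + rnorm(1, 0, 0.06 * s), 0)
  ctrl <- c(tip[1] + rnorm(1, 0, 0.10 * s), 0.45 * tip[2])
  bez <- bezier_points(entry, ctrl, tip, n = 48L)
  for (i in seq_len(nrow(bez) - 1L))
    img <- draw_capsule(img, bez[i, ], bez[i + 1L, ], halfw,
                        -config$tube_intensity / 2)
  # second pass sharpens the tube core
  for (i in seq_len(nrow(bez) - 1L))
    img <- draw_capsule(img, bez[i, ], bez[i + 1L, ], halfw * 0.6,
                        -config$tube_intensity / 2)

  # bright occluders drawn last so some cross (and partially hide) the tube
  if (config$n_occluders > 0L) {
    for (k in seq_len(config$n_occluders)) {
      a <- runif(2, 0.05, 0.95) * s
      b <- a + runif(2, -0.4, 0.4) * s
      img <- draw_capsule(img, a, b, max(1.2, s / 400), 0.22)
    }
  }

  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(s * s, 0, config$noise_sd), s, s)
  img <- pmin(pmax(img, 0), 1)

  lm <- landmarks13(pts, image_size = c(s, s))
  label <- classify_suitability(d_mm)
  structure(list(image = img, landmarks = lm, distance_mm = d_mm,
                 label = label, pixel_spacing = sp, tip = tip,
                 carina = carina, config = config),
            class = "synth_case")
}

#' Stratified 5-fold assignment balanced on the suitability label
#' @param labels character vector of per-image labels
#' @param k number of folds
#' @return integer fold ids in 1..k
#' @export
assign_folds <- function(labels, k = 5L) {
  folds <- integer(length(labels))
  start <- 0L
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    # continue the cycle across label groups so overall fold sizes stay
    # balanced while each label is spread evenly
    folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
    start <- start + length(idx)
  }
  folds
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes one grayscale PNG per case, a COCO-style `annotations.json` (via
#' the annotation schema), and `manifest.csv` with per-image true distances,
#' suitability labels and a stratified 5-fold split.
#'
#' @param config a [synth_config()]
#' @param n_images number of cases (>= 1)
#' @param out_dir output directory (created if missing)
#' @param seed master seed; per-case seeds are derived from it
#' @return the manifest data.frame, invisibly; columns `image_id`,
#'   `file_name`, `distance_mm`, `label`, `fold`
#' @export
generate_dataset <- function(config, n_images, out_dir, seed = 1L) {
  stopifnot(n_images >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  cases <- lapply(case_seeds, function(sd) generate_case(config, seed = sd))
  insts <- lapply(cases, function(cs)
    derive_instances(cs$landmarks, feature_box_size = config$feature_box_size))
  metas <- lapply(seq_along(cases), function(i)
    list(id = i, file_name = sprintf("img_%04d.png", i),
         width = config$image_size, height = config$image_size,
         pixel_spacing = config$pixel_spacing))
  for (i in seq_along(cases))
    write_radiograph(cases[[i]]$image, file.path(out_dir, metas[[i]]$file_name))
  write_coco(to_coco(insts, metas), file.path(out_dir, "annotations.json"))
  labels <- vapply(cases, `[[`, character(1), "label")
  set.seed(seed + 1L)
  manifest <- data.frame(
    image_id = seq_along(cases),
    file_name = vapply(metas, `[[`, character(1), "file_name"),
    distance_mm = vapply(cases, `[[`, numeric(1), "distance_mm"),
    label = labels,
    fold = assign_folds(labels, 5L),
    case_seed = case_seeds)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a generated dataset back into memory
#' @param dir dataset directory written by [generate_dataset()]
#' @return list with `$manifest`, `$coco`, `$instances` (per image id),
#'   and `$image_paths`
#' @export
load_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  coco <- read_coco(file.path(dir, "annotations.json"))
  insts <- from_coco(coco)
  list(manifest = manifest, coco = coco, instances = insts,
       image_paths = setNames(file.path(dir, manifest$file_name),
                              as.character(manifest$image_id)))
}
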