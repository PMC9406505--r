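# Ground-truth data model for the 13-point labelling protocol.
#
# A radiograph is annotated with 13 landmark points: P1-P4 outline the
# distal endotracheal tube (ETT), P5-P13 outline the tracheal bifurcation
# with P9 the Carina feature point. From these the detector's four object
# classes are derived: the ETT box/polygon, the bifurcation box/polygon, and
# two fixed-size square "feature boxes" centered on the ETT tip (midpoint of
# P2 and P3) and on the Carina (P9).
#
# Conventions: 0-based pixel coordinates (x rightward, y downward); boxes are
# half-open [x1, x2) x [y1, y2) in memory and COCO xywh on disk.

#' Construct a validated 13-landmark annotation
#'
#' @param points numeric 13 x 2 matrix (columns x, y) in pixels, 0-based;
#'   rows are P1..P13. P1-P4 lie on the ETT, P5-P13 on the tracheal
#'   bifurcation, with P9 the Carina feature point.
#' @param image_size integer `c(width, height)`; all points must fall inside
#'   `[0, width) x [0, height)`.
#' @return an object of class `landmarks13`
#' @export
landmarks13 <- function(points, image_size = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 13L || ncol(points) != 2L)
    stop("landmarks13: expected a numeric 13 x 2 matrix of points")
  if (any(!is.finite(points)))
    stop("landmarks13: non-finite coordinates")
  if (!is.null(image_size)) {
    if (any(points[, 1] < 0 | points[, 1] >= image_size[1] |
            points[, 2] < 0 | points[, 2] >= image_size[2]))
      stop("landmarks13: points outside image bounds")
  }
  dimnames(points) <- list(paste0("P", 1:13), c("x", "y"))
  structure(list(points = points, image_size = image_size),
            class = "landmarks13")
}

#' Derive the ETT-tip and Carina feature points from the landmarks
#'
#' The ETT tip is the midpoint of P2 and P3; the Carina is P9.
#'
#' @param landmarks a [landmarks13()] object
#' @return list with numeric `ett_tip` and `carina`, each `c(x, y)`
#' @export
derive_feature_points <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmarks13"))
  p <- landmarks$points
  list(ett_tip = unname((p["P2", ] + p["P3", ]) / 2),
       carina = unname(p["P9", ]))
}

# tight axis-aligned half-open bbox of a point set
tight_bbox <- function(pts) {
  c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
}

bbox_area <- function(b) max(0, b[3] - b[1]) * max(0, b[4] - b[2])

#' Re-sequence polygon vertices into a simple polygon
#'
#' Orders vertices by angle about their centroid, which yields a simple
#' (non-self-intersecting) polygon for the star-shaped point sets produced by
#' the labelling protocol. Ties in angle are broken by distance from the
#' centroid.
#' @param pts n x 2 matrix
#' @return n x 2 matrix, re-ordered
#' @export
resequence_polygon <- function(pts) {
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  pts[order(ang, r), , drop = FALSE]
}

# do closed segments (p1,p2) and (p3,p4) properly intersect?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Is a polygon simple (free of proper self-intersections)?
#' @param pts n x 2 vertex matrix, in order
#' @return logical
#' @export
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share a vertex)
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      if (segments_cross(pts[idx[i, 1], ], pts[idx[i, 2], ],
                         pts[idx[j, 1], ], pts[idx[j, 2], ])) return(FALSE)
    }
  }
  TRUE
}

#' Ray-casting point-in-polygon test (boundary counts as inside)
#' @param px,py point coordinates (vectors allowed)
#' @param poly n x 2 vertex matrix
#' @return logical vector
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  res <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]
    # on-edge check
    on <- FALSE
    for (i in seq_len(n)) {
      cr <- (xe[i] - xs[i]) * (y - ys[i]) - (ye[i] - ys[i]) * (x - xs[i])
      if (abs(cr) < 1e-9 &&
          x >= min(xs[i], xe[i]) - 1e-9 && x <= max(xs[i], xe[i]) + 1e-9 &&
          y >= min(ys[i], ye[i]) - 1e-9 && y <= max(ys[i], ye[i]) + 1e-9) {
        on <- TRUE; break
      }
    }
    if (on) { res[k] <- TRUE; next }
    crossings <- ((ys > y) != (ye > y)) &
      (x < (xe - xs) * (y - ys) / (ye - ys) + xs)
    res[k] <- (sum(crossings) %% 2L) == 1L
  }
  res
}

#' Derive detection and segmentation targets from the 13 landmarks
#'
#' Produces the four ground-truth instances: the tight boxes of the ETT
#' (P1-P4) and tracheal bifurcation (P5-P13), square feature boxes of side
#' `feature_box_size` centered on the ETT tip and the Carina, and the two
#' re-sequenced simple polygons. Feature boxes are stored unclipped with
#' their center; clipping to image bounds happens only at COCO export.
#'
#' @param landmarks a [landmarks13()] object
#' @param feature_box_size square box side in pixels (300 at native
#'   full-resolution radiograph scale; scale with image width for smaller
#'   synthetic images)
#' @param image_size `c(width, height)` used at export-time clipping
#' @return object of class `instance_set`: `$boxes` (named list of
#'   `c(x1,y1,x2,y2)`), `$polygons` (ETT, tracheal_bifurcation), `$points`
#'   (ett_tip, carina)
#' @export
derive_instances <- function(landmarks, feature_box_size = 300,
                             image_size = landmarks$image_size) {
  stopifnot(inherits(landmarks, "landmarks13"), feature_box_size > 0)
  p <- landmarks$points
  fp <- derive_feature_points(landmarks)
  ett_box <- tight_bbox(p[1:4, , drop = FALSE])
  bif_box <- tight_bbox(p[5:13, , drop = FALSE])
  if (bbox_area(ett_box) <= 0)
    stop("degenerate annotation: ETT points P1-P4 give a zero-area box")
  if (bbox_area(bif_box) <= 0)
    stop("degenerate annotation: bifurcation points P5-P13 give a zero-area box")
  half <- feature_box_size / 2
  tip_box <- c(fp$ett_tip[1] - half, fp$ett_tip[2] - half,
               fp$ett_tip[1] + half, fp$ett_tip[2] + half)
  car_box <- c(fp$carina[1] - half, fp$carina[2] - half,
               fp$carina[1] + half, fp$carina[2] + half)
  ett_poly <- resequence_polygon(p[1:4, , drop = FALSE])
  bif_poly <- resequence_polygon(p[5:13, , drop = FALSE])
  structure(list(
    boxes = list(ETT = ett_box, ETT_tip = tip_box,
                 tracheal_bifurcation = bif_box, Carina = car_box),
    polygons = list(ETT = ett_poly, tracheal_bifurcation = bif_poly),
    points = list(ett_tip = fp$ett_tip, carina = fp$carina),
    feature_box_size = feature_box_size,
    image_size = image_size), class = "instance_set")
}

#' Box format conversions between in-memory xyxy and COCO xywh
#' @param b numeric length-4 box
#' @return numeric length-4 box in the other convention
#' @export
bbox_xyxy_to_xywh <- function(b) c(b[1], b[2], b[3] - b[1], b[4] - b[2])

#' @rdname bbox_xyxy_to_xywh
#' @export
bbox_xywh_to_xyxy <- function(b) c(b[1], b[2], b[1] + b[3], b[2] + b[4])

clip_box <- function(b, image_size) {
  c(max(b[1], 0), max(b[2], 0),
    min(b[3], image_size[1]), min(b[4], image_size[2]))
}

coco_categories <- function() {
  lapply(seq_along(ETT_CLASSES), function(i)
    list(id = i, name = ETT_CLASSES[i], supercategory = "airway"))
}

#' Serialize instance sets to a COCO-style annotation list
#'
#' @param instances_list list of `instance_set` objects, one per image
#' @param images_meta list of per-image metadata lists with `id`,
#'   `file_name`, `width`, `height` and `pixel_spacing` (mm/px)
#' @return a COCO-style list (`images`, `annotations`, `categories`) ready
#'   for [write_coco()]
#' @export
to_coco <- function(instances_list, images_meta) {
  stopifnot(length(instances_list) == length(images_meta))
  anns <- list()
  aid <- 0L
  for (k in seq_along(instances_list)) {
    inst <- instances_list[[k]]
    meta <- images_meta[[k]]
    isz <- c(meta$width, meta$height)
    for (ci in seq_along(ETT_CLASSES)) {
      cls <- ETT_CLASSES[ci]
      box <- inst$boxes[[cls]]
      clipped <- clip_box(box, isz)
      ann <- list(id = (aid <- aid + 1L), image_id = meta$id, category_id = ci,
                  bbox = as.numeric(bbox_xyxy_to_xywh(clipped)),
                  area = bbox_area(clipped),
                  box_center = as.numeric(c((box[1] + box[3]) / 2,
                                            (box[2] + box[4]) / 2)),
                  box_size = if (cls %in% c("ETT_tip", "Carina"))
                    inst$feature_box_size else NULL,
                  iscrowd = 0L)
      if (cls %in% names(inst$polygons)) {
        poly <- inst$polygons[[cls]]
        ann$segmentation <- list(as.numeric(t(poly)))
      }
      if (cls == "ETT_tip")
        ann$keypoints <- as.numeric(c(inst$points$ett_tip, 2))
      if (cls == "Carina")
        ann$keypoints <- as.numeric(c(inst$points$carina, 2))
      anns[[length(anns) + 1L]] <- ann
    }
  }
  list(images = images_meta, annotations = anns, categories = coco_categories())
}

#' Rebuild instance sets from a COCO-style annotation list
#'
#' Inverse of [to_coco()]: boxes return to xyxy (feature boxes recovered
#' unclipped from the stored center), polygons to vertex matrices, feature
#' points from the keypoint entries.
#'
#' @param coco COCO-style list as produced by [to_coco()] / [read_coco()]
#' @param default_pixel_spacing fallback mm/px used (with a warning) when an
#'   image record carries no `pixel_spacing`
#' @return named list (by image id) of `instance_set` objects, each with
#'   `$pixel_spacing`
#' @export
from_coco <- function(coco, default_pixel_spacing = 0.139) {
  out <- list()
  for (meta in coco$images) {
    isz <- c(meta$width, meta$height)
    spacing <- meta$pixel_spacing
    if (is.null(spacing)) {
      warning("image ", meta$id, ": missing pixel_spacing; using default ",
              default_pixel_spacing, " mm/px")
      spacing <- default_pixel_spacing
    }
    anns <- Filter(function(a) a$image_id == meta$id, coco$annotations)
    if (length(anns) != 4L)
      stop("image ", meta$id, ": expected 4 annotations (one per class), got ",
           length(anns))
    boxes <- list(); polys <- list(); pts <- list()
    fb_size <- NA_real_
    for (a in anns) {
      cls <- ETT_CLASSES[a$category_id]
      box <- bbox_xywh_to_xyxy(as.numeric(a$bbox))
      if (cls %in% c("ETT_tip", "Carina") && !is.null(a$box_center)) {
        # restore the unclipped square around the stored center
        side <- if (!is.null(a$box_size)) as.numeric(a$box_size)
                else max(box[3] - box[1], box[4] - box[2])
        ctr <- as.numeric(a$box_center)
        box <- c(ctr[1] - side / 2, ctr[2] - side / 2,
                 ctr[1] + side / 2, ctr[2] + side / 2)
        fb_size <- side
      }
      boxes[[cls]] <- box
      if (!is.null(a$segmentation)) {
        v <- as.numeric(a$segmentation[[1]])
        polys[[cls]] <- matrix(v, ncol = 2, byrow = TRUE,
                               dimnames = list(NULL, c("x", "y")))
      }
      if (!is.null(a$keypoints)) {
        kp <- as.numeric(a$keypoints)
        pts[[if (cls == "ETT_tip") "ett_tip" else "carina"]] <- kp[1:2]
      }
    }
    inst <- structure(list(boxes = boxes[ETT_CLASSES], polygons = polys,
                           points = pts, feature_box_size = fb_size,
                           image_size = isz, pixel_spacing = spacing),
                      class = "instance_set")
    out[[as.character(meta$id)]] <- inst
  }
  out
}

#' Read / write COCO-style JSON
#' @param path JSON file path
#' @return for `read_coco`, the COCO-style list
#' @export
read_coco <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' @rdname read_coco
#' @param coco COCO-style list
#' @export
write_coco <- function(coco, path) {
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a grayscale PNG radiograph as an (H, W) intensity matrix in [0, 1]
#' @param path PNG file
#' @return numeric H x W matrix
#' @export
read_radiograph <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write an (H, W) intensity matrix in [0, 1] to a grayscale PNG
#' @param img numeric matrix
#' @param path output path
#' @export
write_radiograph <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
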