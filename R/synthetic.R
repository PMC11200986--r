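# Deterministic synthetic quadruped scenes with exact keypoint ground truth.
#
# Each instance is a parameterized stick-figure quadruped: a canonical joint
# layout per schema, jittered by per-instance rotation/pose noise, scaled to
# hit a target area class (medium 32^2 <= area <= 96^2, large > 96^2), and
# rendered with a distinct marker color per keypoint over a textured
# background. Annotations are the exact generator coordinates, so a perfect
# predictor has zero localization error by construction.

#' Configuration for the synthetic dataset generator
#'
#' @param n_images number of images to generate.
#' @param image_size image side in px, or c(H, W).
#' @param instances_per_image inclusive integer range c(lo, hi).
#' @param scale_mix named fractions for `medium` and `large` instances
#'   (summing to at most 1; the remainder becomes small instances with
#'   area < 32^2). Classes follow the area partition 32^2 <= area <= 96^2
#'   (medium) and area > 96^2 (large).
#' @param occlusion_rate probability that a labeled keypoint is occluded
#'   (v = 1: annotated, drawn, then covered by a patch).
#' @param unlabeled_rate probability that a keypoint is unlabeled (v = 0:
#'   not rendered, coordinates zeroed).
#' @param seed integer seed; generation is fully reproducible, with one
#'   counter-derived substream per image.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_images = 16L, image_size = 256L,
                         instances_per_image = c(1L, 2L),
                         scale_mix = c(medium = 0.5, large = 0.5),
                         occlusion_rate = 0.1, unlabeled_rate = 0.0,
                         seed = 1L) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  if (length(instances_per_image) == 1L)
    instances_per_image <- rep(instances_per_image, 2L)
  scale_mix <- c(medium = unname(scale_mix["medium"] %||% 0),
                 large = unname(scale_mix["large"] %||% 0))
  if (any(scale_mix < 0) || sum(scale_mix) > 1 + 1e-9)
    stop("scale_mix fractions must be non-negative and sum to at most 1")
  if (occlusion_rate < 0 || occlusion_rate > 1) stop("occlusion_rate must be in [0,1]")
  if (unlabeled_rate < 0 || unlabeled_rate > 1) stop("unlabeled_rate must be in [0,1]")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 instances_per_image = as.integer(instances_per_image),
                 scale_mix = scale_mix,
                 occlusion_rate = occlusion_rate,
                 unlabeled_rate = unlabeled_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Canonical joint layout in the unit square (x rightward, y downward), side
# view facing right. Keyed by landmark name so both registered schemas and
# any custom schema reusing these names get a plausible quadruped.
.canonical_joints <- list(
  "left eye" = c(0.84, 0.16), "right eye" = c(0.89, 0.13),
  "left ear base" = c(0.80, 0.08), "right ear base" = c(0.86, 0.06),
  "nose" = c(0.98, 0.24), "neck" = c(0.74, 0.28), "throat" = c(0.84, 0.35),
  "withers" = c(0.55, 0.25),
  "root of tail" = c(0.08, 0.30), "tail base" = c(0.08, 0.30),
  "left shoulder" = c(0.62, 0.42), "right shoulder" = c(0.70, 0.40),
  "left elbow" = c(0.60, 0.60), "right elbow" = c(0.72, 0.58),
  "left front paw" = c(0.58, 0.90), "right front paw" = c(0.74, 0.88),
  "left hip" = c(0.13, 0.45), "right hip" = c(0.22, 0.43),
  "left knee" = c(0.15, 0.63), "right knee" = c(0.27, 0.61),
  "left back paw" = c(0.11, 0.90), "right back paw" = c(0.29, 0.88),
  "left front elbow" = c(0.60, 0.55), "right front elbow" = c(0.72, 0.53),
  "left back elbow" = c(0.14, 0.53), "right back elbow" = c(0.23, 0.51),
  "left front knee" = c(0.58, 0.72), "right front knee" = c(0.74, 0.70),
  "left back knee" = c(0.13, 0.72), "right back knee" = c(0.26, 0.70))

# joint layout for a schema: canonical where named, otherwise a circle
.schema_layout <- function(schema) {
  u <- matrix(NA_real_, schema$M, 2L)
  for (m in seq_len(schema$M)) {
    p <- .canonical_joints[[schema$keypoint_names[m]]]
    if (!is.null(p)) u[m, ] <- p
  }
  miss <- which(is.na(u[, 1L]))
  if (length(miss)) {
    th <- 2 * pi * (seq_along(miss) - 1L) / max(1L, length(miss))
    u[miss, ] <- cbind(0.5 + 0.4 * cos(th), 0.5 + 0.4 * sin(th))
  }
  u
}

.kp_colors <- function(M) {
  h <- (seq_len(M) - 1L) / M
  grDevices::col2rgb(grDevices::hsv(h, s = 1, v = 1)) / 255
}

.blank_image <- function(H, W) array(0, dim = c(H, W, 3L))

.draw_disk <- function(img, x, y, r, col) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  rows <- max(1L, floor(y - r + 1)):min(H, ceiling(y + r + 1))
  cols <- max(1L, floor(x - r + 1)):min(W, ceiling(x + r + 1))
  if (!length(rows) || !length(cols)) return(img)
  dy <- (rows - 0.5) - y; dx <- (cols - 0.5) - x
  mask <- outer(dy^2, dx^2, "+") <= r^2
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[mask] <- col[ch]
    img[rows, cols, ch] <- plane
  }
  img
}

.draw_segment <- function(img, x0, y0, x1, y1, hw, col) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  rows <- max(1L, floor(min(y0, y1) - hw)):min(H, ceiling(max(y0, y1) + hw + 1))
  cols <- max(1L, floor(min(x0, x1) - hw)):min(W, ceiling(max(x0, x1) + hw + 1))
  if (!length(rows) || !length(cols)) return(img)
  PX <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
  PY <- matrix(rows - 0.5, length(rows), length(cols))
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx^2 + dy^2
  tt <- if (L2 == 0) 0 else pmin(pmax(((PX - x0) * dx + (PY - y0) * dy) / L2, 0), 1)
  mask <- (PX - (x0 + tt * dx))^2 + (PY - (y0 + tt * dy))^2 <= hw^2
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[mask] <- col[ch]
    img[rows, cols, ch] <- plane
  }
  img
}

# low-frequency textured background, deterministic under the current RNG
.textured_background <- function(H, W) {
  gx <- outer(rep(1, H), seq(0, 1, length.out = W))
  gy <- outer(seq(0, 1, length.out = H), rep(1, W))
  ph <- stats::runif(6L, 0, 2 * pi)
  fr <- stats::runif(2L, 2, 5)
  tex <- 0.5 + 0.08 * sin(2 * pi * fr[1L] * gx + ph[1L]) +
    0.08 * cos(2 * pi * fr[2L] * gy + ph[2L]) +
    0.04 * sin(2 * pi * (gx + gy) * fr[1L] + ph[3L])
  base <- stats::runif(3L, 0.25, 0.55)
  img <- .blank_image(H, W)
  for (ch in 1:3) img[, , ch] <- pmin(1, pmax(0, tex * base[ch]))
  img
}

# sample one instance: jittered joints scaled to an exact target area
.sample_instance <- function(schema, layout, img_hw, scale_mix) {
  H <- img_hw[1L]; W <- img_hw[2L]
  u <- stats::runif(1L)
  cls <- if (u < scale_mix["medium"]) "medium"
  else if (u < sum(scale_mix)) "large" else "small"
  # pose jitter in unit space
  ang <- stats::rnorm(1L, 0, 0.08)
  jit <- matrix(stats::rnorm(2L * schema$M, 0, 0.015), ncol = 2L)
  uj <- layout + jit
  ctr <- colMeans(uj)
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  uj <- sweep(sweep(uj, 2L, ctr) %*% rot, 2L, ctr, "+")
  pad <- 0.06
  ux <- range(uj[, 1L]); uy <- range(uj[, 2L])
  uw <- diff(ux) + 2 * pad; uh <- diff(uy) + 2 * pad
  # feasible sqrt-area given the frame (keep a safety margin of 2 px)
  smax_fit <- sqrt((W - 2) * (H - 2) * min(uw, uh) / max(uw, uh))
  rng <- switch(cls,
    small  = c(16, 30),
    medium = c(40, 88),
    large  = c(104, 180))
  rng[2L] <- min(rng[2L], smax_fit)
  if (rng[2L] <= rng[1L])
    stop(sprintf("a %s-scale instance does not fit a %dx%d image", cls, H, W))
  s_target <- stats::runif(1L, rng[1L], rng[2L])
  area <- s_target^2
  L <- sqrt(area / (uw * uh))          # px per unit; bbox area == area exactly
  bw <- uw * L; bh <- uh * L
  bx <- stats::runif(1L, 1, W - bw - 1)
  by <- stats::runif(1L, 1, H - bh - 1)
  kp_xy <- cbind(bx + (uj[, 1L] - ux[1L] + pad) * L,
                 by + (uj[, 2L] - uy[1L] + pad) * L)
  list(kp_xy = kp_xy, bbox = c(bx, by, bw, bh), area = area, class = cls,
       scale_px = L)
}

.render_instance <- function(img, inst, schema, occl_xy, kp_v) {
  cols <- .kp_colors(schema$M)
  body_col <- c(0.45, 0.30, 0.15)
  r_joint <- max(2, 0.035 * sqrt(inst$area))
  r_limb <- max(1, 0.018 * sqrt(inst$area))
  if (!is.null(schema$skeleton)) {
    for (e in seq_len(nrow(schema$skeleton))) {
      a <- schema$skeleton[e, 1L] + 1L; b <- schema$skeleton[e, 2L] + 1L
      if (kp_v[a] > 0 && kp_v[b] > 0)
        img <- .draw_segment(img, inst$kp_xy[a, 1L], inst$kp_xy[a, 2L],
                             inst$kp_xy[b, 1L], inst$kp_xy[b, 2L], r_limb, body_col)
    }
  }
  for (m in seq_len(schema$M)) {
    if (kp_v[m] > 0)
      img <- .draw_disk(img, inst$kp_xy[m, 1L], inst$kp_xy[m, 2L], r_joint, cols[, m])
  }
  # occluders: flat gray patches over v = 1 keypoints, drawn last
  if (length(occl_xy)) {
    for (i in seq_len(nrow(occl_xy)))
      img <- .draw_disk(img, occl_xy[i, 1L], occl_xy[i, 2L],
                        1.6 * r_joint, c(0.5, 0.5, 0.5))
  }
  img
}

#' Generate a synthetic quadruped keypoint dataset
#'
#' Renders `cfg$n_images` scenes of stick-figure quadrupeds with exact
#' keypoint annotations and writes them as PNG files plus one COCO keypoint
#' JSON (`annotations.json`) under `dir`. Instance areas are drawn to satisfy
#' `cfg$scale_mix` against the medium/large area partition; generation is a
#' pure function of `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param schema a [keypoint_schema()]; defaults to the 17-keypoint "ap10k"
#'   schema.
#' @param dir output directory (created if missing).
#' @return the generated [annotation_set()], invisibly carrying the image
#'   directory as attribute `"dir"`.
#' @export
generate_synthetic_dataset <- function(cfg, schema = load_keypoint_schema("ap10k"),
                                       dir = tempfile("synthpose")) {
  stopifnot(inherits(cfg, "synth_config"), inherits(schema, "keypoint_schema"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- .schema_layout(schema)
  H <- cfg$image_size[1L]; W <- cfg$image_size[2L]
  images <- data.frame(id = integer(), file_name = character(),
                       width = integer(), height = integer())
  anns <- list(); ann_id <- 0L
  for (i in seq_len(cfg$n_images)) {
    set.seed((cfg$seed * 2654435L + i * 7919L) %% 2147483647L)
    img <- .textured_background(H, W)
    n_inst <- sample(seq(cfg$instances_per_image[1L], cfg$instances_per_image[2L]), 1L)
    for (k in seq_len(n_inst)) {
      inst <- .sample_instance(schema, layout, c(H, W), cfg$scale_mix)
      v <- rep(2, schema$M)
      v[stats::runif(schema$M) < cfg$unlabeled_rate] <- 0
      occl <- stats::runif(schema$M) < cfg$occlusion_rate & v == 2
      v[occl] <- 1
      img <- .render_instance(img, inst, schema,
                              inst$kp_xy[occl, , drop = FALSE], v)
      kp <- cbind(inst$kp_xy, v)
      kp[v == 0, 1:2] <- 0
      ann_id <- ann_id + 1L
      anns[[ann_id]] <- coco_annotation(image_id = i, keypoints = kp,
                                        bbox = inst$bbox, area = inst$area,
                                        id = ann_id)
    }
    fn <- sprintf("synth_%04d.png", i)
    png::writePNG(img, file.path(dir, fn))
    images <- rbind(images, data.frame(id = i, file_name = fn, width = W, height = H))
  }
  aset <- annotation_set(images, anns, schema)
  write_coco_keypoints(aset, file.path(dir, "annotations.json"))
  attr(aset, "dir") <- dir
  invisible(aset)
}

#' Overlay keypoints and skeleton on an image
#'
#' Draws one marker per labeled keypoint (v > 0) and one line segment per
#' skeleton edge whose endpoints are both labeled; unlabeled keypoints are
#' not drawn. The returned image carries attributes `n_markers` and
#' `n_segments` with the number of primitives drawn.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param keypoints M x 3 matrix (x, y, v).
#' @param schema a [keypoint_schema()].
#' @param radius marker radius in px.
#' @return the annotated image array.
#' @export
render_skeleton_overlay <- function(image, keypoints, schema, radius = 2.5) {
  keypoints <- matrix(as.numeric(keypoints), ncol = 3L)
  if (nrow(keypoints) != schema$M) stop("keypoints must have one row per schema keypoint")
  cols <- .kp_colors(schema$M)
  v <- keypoints[, 3L]
  n_seg <- 0L
  if (!is.null(schema$skeleton)) {
    for (e in seq_len(nrow(schema$skeleton))) {
      a <- schema$skeleton[e, 1L] + 1L; b <- schema$skeleton[e, 2L] + 1L
      if (v[a] > 0 && v[b] > 0) {
        image <- .draw_segment(image, keypoints[a, 1L], keypoints[a, 2L],
                               keypoints[b, 1L], keypoints[b, 2L],
                               radius * 0.4, c(1, 1, 1))
        n_seg <- n_seg + 1L
      }
    }
  }
  n_mark <- 0L
  for (m in seq_len(schema$M)) {
    if (v[m] > 0) {
      image <- .draw_disk(image, keypoints[m, 1L], keypoints[m, 2L], radius, cols[, m])
      n_mark <- n_mark + 1L
    }
  }
  attr(image, "n_markers") <- n_mark
  attr(image, "n_segments") <- n_seg
  image
}

#' Crop a bounding box and resize by bilinear interpolation
#'
#' Top-down models operate on per-instance crops: the bbox region is resampled
#' to `out_size` px using the pixel-center convention (source pixel (r, c)
#' covers [c, c+1) x [r, r+1) with center (c+0.5, r+0.5)). The returned crop
#' carries the affine keypoint transform as attributes `scale` and `offset`:
#' `crop_xy = (xy - offset) * scale`.
#'
#' @param image H x W x 3 array.
#' @param bbox (x, y, w, h) in px.
#' @param out_size output side in px (square crop).
#' @return out_size x out_size x 3 array with transform attributes.
#' @export
crop_resize <- function(image, bbox, out_size) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  bx <- bbox[1L]; by <- bbox[2L]; bw <- bbox[3L]; bh <- bbox[4L]
  if (bw <= 0 || bh <= 0) stop("bbox must have positive size")
  sx <- out_size / bw; sy <- out_size / bh
  xs <- bx + (seq_len(out_size) - 0.5) / sx
  ys <- by + (seq_len(out_size) - 0.5) / sy
  cx <- pmin(pmax(xs - 0.5, 0), W - 1)   # continuous pixel-index coordinates
  cy <- pmin(pmax(ys - 0.5, 0), H - 1)
  x0 <- pmin(floor(cx), W - 2); x1 <- x0 + 1; fx <- cx - x0
  y0 <- pmin(floor(cy), H - 2); y1 <- y0 + 1; fy <- cy - y0
  out <- array(0, dim = c(out_size, out_size, 3L))
  wx0 <- 1 - fx; wy0 <- 1 - fy
  for (ch in 1:3) {
    pl <- image[, , ch]
    P00 <- pl[y0 + 1, x0 + 1, drop = FALSE]
    P01 <- pl[y0 + 1, x1 + 1, drop = FALSE]
    P10 <- pl[y1 + 1, x0 + 1, drop = FALSE]
    P11 <- pl[y1 + 1, x1 + 1, drop = FALSE]
    out[, , ch] <- outer(wy0, wx0) * P00 + outer(wy0, fx) * P01 +
      outer(fy, wx0) * P10 + outer(fy, fx) * P11
  }
  attr(out, "scale") <- c(sx, sy)
  attr(out, "offset") <- c(bx, by)
  out
}
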