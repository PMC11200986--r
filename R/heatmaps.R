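# Target heatmap construction, the heatmap prediction head, and decoding of
# heatmaps back to image coordinates.
#
# Heatmaps live at twice the feature-grid resolution by default: the head is
# a per-cell two-layer network over the concatenated channels [I, S] whose
# last layer emits a 2x2 block of heatmap values per grid cell (a stride-2
# transposed convolution with a 2x2 kernel). Heatmap cell (i, j) has its
# center at ((j + 0.5) * stride, (i + 0.5) * stride) image px.

#' Heatmap set container
#'
#' @param maps M x H' x W' array of per-keypoint score maps.
#' @param stride image px per heatmap cell.
#' @return object of class `heatmap_set`.
#' @export
heatmap_set <- function(maps, stride) {
  stopifnot(length(dim(maps)) == 3L, stride > 0, all(is.finite(maps)))
  structure(list(maps = maps, stride = stride), class = "heatmap_set")
}

#' Build ground-truth Gaussian heatmaps
#'
#' Each labeled keypoint (v > 0) yields an unnormalized Gaussian of width
#' `sigma_h` (in heatmap cells) centered at the keypoint's continuous cell
#' position, with peak value 1 when the keypoint sits exactly on a cell
#' center; unlabeled keypoints yield all-zero maps. A labeled keypoint
#' falling outside the map yields a zero map with a warning.
#'
#' @param keypoints M x 3 matrix (x, y, v) in *heatmap cell* coordinates:
#'   cell (i, j) has center (x = j, y = i), 0-based. Callers working in image
#'   px convert via `cell = px / stride - 0.5`.
#' @param shape c(H', W') heatmap size in cells.
#' @param sigma_h Gaussian width in cells (default 2).
#' @param stride image px per heatmap cell recorded in the result (default 1).
#' @return a [heatmap_set()].
#' @export
make_target_heatmaps <- function(keypoints, shape, sigma_h = 2, stride = 1) {
  if (sigma_h <= 0) stop("sigma_h must be positive")
  keypoints <- matrix(as.numeric(keypoints), ncol = 3L)
  M <- nrow(keypoints)
  Hh <- shape[1L]; Wh <- shape[2L]
  maps <- array(0, dim = c(M, Hh, Wh))
  cj <- matrix(rep(seq_len(Wh) - 1L, each = Hh), Hh, Wh)
  ci <- matrix(rep(seq_len(Hh) - 1L, times = Wh), Hh, Wh)
  for (m in seq_len(M)) {
    if (keypoints[m, 3L] == 0) next
    kx <- keypoints[m, 1L]; ky <- keypoints[m, 2L]
    if (kx < -0.5 || kx > Wh - 0.5 || ky < -0.5 || ky > Hh - 0.5) {
      warning(sprintf("keypoint %d lies outside the heatmap; target left zero", m))
      next
    }
    maps[m, , ] <- exp(-((cj - kx)^2 + (ci - ky)^2) / (2 * sigma_h^2))
  }
  heatmap_set(maps, stride)
}

#' Initialize heatmap-head parameters
#'
#' Per-cell two-layer network over concatenated [image features, spatial
#' similarity] channels; the output layer emits 4 values per keypoint per
#' grid cell, arranged as the cell's 2x2 block of the upsampled heatmap.
#'
#' @param d_in input channel count (D_I + M).
#' @param M number of keypoints.
#' @param hidden hidden width.
#' @param seed initialization seed.
#' @param upsample upsampling factor (currently 2).
#' @return parameter list.
#' @export
heatmap_head_params <- function(d_in, M, hidden = 48L, seed = 1L, upsample = 2L) {
  if (upsample != 2L) stop("only 2x heatmap upsampling is implemented")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  list(W1 = .init_mat(d_in, hidden), b1 = matrix(0, 1L, hidden),
       W2 = .init_mat(hidden, 4L * M, 0.01), b2 = matrix(0, 1L, 4L * M),
       M = as.integer(M), upsample = 2L)
}

# graph-space head: X (G^2 x (D_I + M)) -> blocks (G^2 x 4M)
ag_heatmap_head <- function(I_tokens, S_t_node, head) {
  X <- ag_cbind(I_tokens, ag_t(S_t_node))
  h <- ag_relu(ag_affine(X, head$W1, head$b1))
  ag_affine(h, head$W2, head$b2)
}

# block layout <-> heatmap stacks.
# blocks: G^2 x 4M, cells row-major; columns (m-1)*4 + (di*2 + dj) + 1 map to
# heatmap cell (2i + di, 2j + dj) of keypoint m.
blocks_to_maps <- function(blocks, grid_h, grid_w, M) {
  maps <- array(0, dim = c(M, 2L * grid_h, 2L * grid_w))
  for (m in seq_len(M)) for (di in 0:1) for (dj in 0:1) {
    col <- (m - 1L) * 4L + di * 2L + dj + 1L
    sub <- matrix(blocks[, col], grid_h, grid_w, byrow = TRUE)
    maps[m, seq(1L + di, 2L * grid_h, by = 2L), seq(1L + dj, 2L * grid_w, by = 2L)] <- sub
  }
  maps
}

maps_to_blocks <- function(maps, grid_h, grid_w) {
  M <- dim(maps)[1L]
  blocks <- matrix(0, grid_h * grid_w, 4L * M)
  for (m in seq_len(M)) for (di in 0:1) for (dj in 0:1) {
    col <- (m - 1L) * 4L + di * 2L + dj + 1L
    sub <- maps[m, seq(1L + di, 2L * grid_h, by = 2L), seq(1L + dj, 2L * grid_w, by = 2L)]
    blocks[, col] <- as.numeric(t(sub))
  }
  blocks
}

#' Predict heatmaps from image features and spatial similarity
#'
#' Concatenates the image feature map with the M spatial-similarity channels
#' and applies the heatmap head, producing one map per keypoint at twice the
#' grid resolution. Deterministic given parameters and inputs.
#'
#' @param I H x W x D_I image feature array.
#' @param S M x H x W spatial-similarity array (or M x (H*W) matrix).
#' @param head parameters from [heatmap_head_params()].
#' @param patch_size image px per feature cell (fixes the heatmap stride).
#' @return a [heatmap_set()] with stride `patch_size / 2`.
#' @export
predict_heatmaps <- function(I, S, head, patch_size = 4L) {
  gh <- dim(I)[1L]; gw <- dim(I)[2L]
  Sm <- .as_kp_matrix(S)
  if (ncol(Sm) != gh * gw) stop("S grid does not match the feature map")
  if (nrow(Sm) != head$M) stop("S keypoint count does not match the head")
  blocks <- ag_value(ag_heatmap_head(ag_const(.as_cell_matrix(I)),
                                     ag_const(Sm), lapply_nodes(head)))
  heatmap_set(blocks_to_maps(blocks, gh, gw, head$M), patch_size / 2)
}

#' Decode heatmaps to keypoint coordinates
#'
#' Per map: the argmax cell (ties broken toward the smallest (row, col)
#' lexicographically) plus a quarter-cell shift toward the larger of the two
#' axis neighbors, mapped to image px by the cell-center convention. The
#' score is the peak value; an all-zero (or non-positive) map decodes to
#' (0, 0) with score 0 and v = 0.
#'
#' @param hset a [heatmap_set()].
#' @return M x 3 matrix (x px, y px, score).
#' @export
decode_heatmaps <- function(hset) {
  stopifnot(inherits(hset, "heatmap_set"))
  maps <- hset$maps; stride <- hset$stride
  M <- dim(maps)[1L]; Hh <- dim(maps)[2L]; Wh <- dim(maps)[3L]
  out <- matrix(0, M, 3L)
  for (m in seq_len(M)) {
    mp <- maps[m, , , drop = TRUE]
    mp <- matrix(mp, Hh, Wh)
    pk <- max(mp)
    if (pk <= 0) next
    hits <- which(mp == pk, arr.ind = TRUE)
    best <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    r <- best[1L]; cc <- best[2L]
    right <- if (cc < Wh) mp[r, cc + 1L] else -Inf
    left  <- if (cc > 1L) mp[r, cc - 1L] else -Inf
    down  <- if (r < Hh) mp[r + 1L, cc] else -Inf
    up    <- if (r > 1L) mp[r - 1L, cc] else -Inf
    sx <- if (right > left) 0.25 else if (left > right) -0.25 else 0
    sy <- if (down > up) 0.25 else if (up > down) -0.25 else 0
    out[m, ] <- c((cc - 1L + 0.5 + sx) * stride, (r - 1L + 0.5 + sy) * stride, pk)
  }
  out
}
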