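# Contrastive text-image matching, spatial similarity maps, and the
# composite training loss
#   L = L_heatmap + beta * L_match + beta * L_spatial,  beta = 2 by default,
# where L_match is the symmetric cross-entropy between the row-softmaxed
# cosine matrix Q (and its transpose) and the diagonal target assignment.

#' Cosine similarity matrix between prompts and keypoint features
#'
#' `Q[m, n]` is the cosine of the m-th prompt embedding and the n-th
#' keypoint-local feature; the diagonal holds the matched pairs. Entries lie
#' in [-1, 1]; the closer a diagonal entry is to 1, the better that
#' keypoint's text and image features agree.
#'
#' @param P_prompt M x D matrix.
#' @param I_keypoint M x D matrix (any row count N is allowed, giving M x N).
#' @return cosine matrix.
#' @export
cosine_similarity_matrix <- function(P_prompt, I_keypoint) {
  if (any(sqrt(rowSums(P_prompt^2)) == 0) || any(sqrt(rowSums(I_keypoint^2)) == 0))
    stop("cannot L2-normalize a zero-norm row")
  ag_value(ag_matmul(ag_normalize_rows(ag_const(P_prompt)),
                     ag_t(ag_normalize_rows(ag_const(I_keypoint)))))
}

#' Spatial similarity maps between prompts and the projected feature map
#'
#' `S[m, i, j]` is the cosine of prompt m and the projected feature at grid
#' cell (i, j): the text-conditioned probability landscape of where keypoint
#' m sits in the image.
#'
#' @param P_prompt M x D matrix.
#' @param I_p H x W x D array (or cell matrix, returning M x (H*W)).
#' @return M x H x W array of cosines (entries in [-1, 1]).
#' @export
spatial_similarity_map <- function(P_prompt, I_p) {
  was_mat <- is.matrix(I_p)
  m <- .as_cell_matrix(I_p)
  if (any(sqrt(rowSums(P_prompt^2)) == 0) || any(sqrt(rowSums(m^2)) == 0))
    stop("cannot L2-normalize a zero-norm row")
  Sm <- ag_value(ag_matmul(ag_normalize_rows(ag_const(P_prompt)),
                           ag_t(ag_normalize_rows(ag_const(m)))))
  if (was_mat) return(Sm)
  H <- dim(I_p)[1L]; W <- dim(I_p)[2L]
  out <- array(0, dim = c(nrow(Sm), H, W))
  for (mm in seq_len(nrow(Sm))) out[mm, , ] <- matrix(Sm[mm, ], H, W, byrow = TRUE)
  out
}

# graph-space symmetric diagonal cross-entropy on temperature-scaled cosines
ag_matching_loss <- function(Q, inv_temp) {
  logits <- ag_scalar_mul(Q, inv_temp)
  ag_scale(ag_add(ag_ce_diag(logits), ag_ce_diag(ag_t(logits))), 0.5)
}

#' Symmetric contrastive matching loss
#'
#' One half of the sum of two diagonal cross-entropies: rows of `Q`
#' (text-anchored) and rows of `t(Q)` (image-anchored), each row-softmaxed
#' after scaling by `1/temperature`, scored against the identity assignment.
#' The published objective carries no temperature; the scaling (default 1,
#' i.e. raw cosines) is standard contrastive practice and is exposed as
#' explicit configuration.
#'
#' @param Q square cosine matrix.
#' @param temperature positive softmax temperature.
#' @return scalar loss.
#' @export
matching_loss <- function(Q, temperature = 1) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  if (temperature <= 0) stop("temperature must be positive")
  ag_value(ag_matching_loss(ag_const(Q), ag_const(matrix(1 / temperature))))[1L]
}

#' Gaussian spatial targets on the feature grid
#'
#' The target spatial distribution S_t for keypoint m is a 2-D Gaussian in
#' feature-cell units centered on the keypoint's (continuous) grid position,
#' scaled to peak 1 so it lives on the cosine scale; unlabeled keypoints get
#' an all-zero row.
#'
#' @param keypoints M x 3 (x px, y px, v) in encoder-input pixels.
#' @param grid_h,grid_w feature-grid size.
#' @param patch_size image px per feature cell.
#' @param sigma Gaussian width in cells.
#' @return M x (grid_h * grid_w) matrix.
#' @export
spatial_targets <- function(keypoints, grid_h, grid_w, patch_size, sigma = 1) {
  M <- nrow(keypoints)
  out <- matrix(0, M, grid_h * grid_w)
  cj <- rep(seq_len(grid_w) - 1L, times = grid_h)
  ci <- rep(seq_len(grid_h) - 1L, each = grid_w)
  for (m in seq_len(M)) {
    if (keypoints[m, 3L] == 0) next
    cx <- keypoints[m, 1L] / patch_size - 0.5
    cy <- keypoints[m, 2L] / patch_size - 0.5
    out[m, ] <- exp(-((cj - cx)^2 + (ci - cy)^2) / (2 * sigma^2))
  }
  out
}

#' Composite training loss
#'
#' `total = heatmap_mse + beta * matching_ce + beta * spatial_mse`, with all
#' three sums restricted to labeled keypoints (v > 0) and normalized by the
#' labeled count rather than M. Heatmaps and spatial maps are compared by
#' per-keypoint summed squared error; the matching term is the symmetric
#' diagonal cross-entropy restricted to the labeled-by-labeled submatrix of
#' `Q`.
#'
#' @param h_pred,h_t predicted / target heatmaps: M x K matrices (rows =
#'   keypoints, columns = flattened heatmap cells) or M x H x W arrays.
#' @param Q square cosine matrix over all M keypoints.
#' @param S,S_t predicted / target spatial maps, same shape rules as the
#'   heatmaps.
#' @param beta weight of the matching and spatial terms (default 2).
#' @param mask logical vector of labeled keypoints (default all).
#' @param temperature softmax temperature of the matching term.
#' @return object of class `loss_breakdown`: list(heatmap_mse, matching_ce,
#'   spatial_mse, beta, total).
#' @export
total_loss <- function(h_pred, h_t, Q, S, S_t, beta = 2, mask = NULL,
                       temperature = 1) {
  if (beta < 0) stop("beta must be non-negative")
  h_pred <- .as_kp_matrix(h_pred); h_t <- .as_kp_matrix(h_t)
  S <- .as_kp_matrix(S); S_t <- .as_kp_matrix(S_t)
  M <- nrow(h_pred)
  if (is.null(mask)) mask <- rep(TRUE, M)
  if (!all(dim(h_pred) == dim(h_t)) || !all(dim(S) == dim(S_t)) ||
      nrow(S) != M || nrow(Q) != M || ncol(Q) != M)
    stop("shape mismatch between loss inputs")
  hm <- ag_value(ag_masked_sse_mean(ag_const(h_pred), h_t, mask))[1L]
  sp <- ag_value(ag_masked_sse_mean(ag_const(S), S_t, mask))[1L]
  vis <- which(mask)
  ce <- if (length(vis) > 0L)
    matching_loss(Q[vis, vis, drop = FALSE], temperature) else 0
  loss_breakdown(hm, ce, sp, beta)
}

.as_kp_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) != 3L) stop("expected a matrix or an M x H x W array")
  out <- matrix(0, d[1L], d[2L] * d[3L])
  for (m in seq_len(d[1L])) out[m, ] <- as.numeric(t(x[m, , ]))
  out
}

#' Assemble a loss breakdown record
#'
#' @param heatmap_mse,matching_ce,spatial_mse non-negative component values.
#' @param beta weight of the matching and spatial terms.
#' @return object of class `loss_breakdown`; `total` always equals
#'   `heatmap_mse + beta * matching_ce + beta * spatial_mse`.
#' @export
loss_breakdown <- function(heatmap_mse, matching_ce, spatial_mse, beta = 2) {
  stopifnot(is.finite(heatmap_mse), is.finite(matching_ce), is.finite(spatial_mse))
  structure(list(heatmap_mse = heatmap_mse, matching_ce = matching_ce,
                 spatial_mse = spatial_mse, beta = beta,
                 total = heatmap_mse + beta * matching_ce + beta * spatial_mse),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.5f = heatmap %.5f + %.1f x (matching %.5f + spatial %.5f)\n",
              x$total, x$heatmap_mse, x$beta, x$matching_ce, x$spatial_mse))
  invisible(x)
}
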