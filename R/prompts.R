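# Dynamic conditional prompts: learnable context vectors, the image-
# conditioned token alpha produced by a small non-linear meta-network, and
# the assembly of per-keypoint prompt sequences.
#
# For one image, the q context vectors V_i are shifted by a single
# image-conditioned token alpha = g(mean-pool(I_p)), giving conditional
# tokens V_i + alpha shared across all M keypoints; each keypoint's prompt
# sequence is these q rows followed by its embedded sentence tokens.

#' Create a prompt context (context vectors + meta-network)
#'
#' Holds the q learnable context vectors (width `e`, the token-embedding
#' width) and the parameters of the meta-network `g`: two affine layers with
#' a ReLU in between and a bottleneck of `hidden` units mapping the pooled
#' projected image feature (width `D`) to a single token of width `e`.
#'
#' @param q context length (number of conditional tokens); default 8.
#' @param e token-embedding width.
#' @param D projected image-feature width (meta-network input).
#' @param hidden bottleneck width of the meta-network; defaults to
#'   `max(4, D %/% 16)`.
#' @param seed seed for parameter initialization.
#' @param init_sd standard deviation of the Gaussian initialization.
#' @return object of class `prompt_context`: list with `context_vectors`
#'   (q x e) and `meta_net` (W1, b1, W2, b2).
#' @export
prompt_context <- function(q = 8L, e = 32L, D = e, hidden = max(4L, D %/% 16L),
                           seed = 1L, init_sd = 0.02) {
  if (q < 1L) stop("context length q must be at least 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ctx <- list(
    q = as.integer(q), e = as.integer(e), D = as.integer(D),
    context_vectors = matrix(stats::rnorm(q * e, 0, init_sd), q, e),
    meta_net = list(
      W1 = matrix(stats::rnorm(D * hidden, 0, init_sd), D, hidden),
      b1 = matrix(0, 1L, hidden),
      W2 = matrix(stats::rnorm(hidden * e, 0, init_sd), hidden, e),
      b2 = matrix(0, 1L, e)))
  structure(ctx, class = "prompt_context")
}

# graph-space forward of the meta-network on an (H*W) x D projected map node
ag_conditional_token <- function(Ip, meta) {
  pooled <- ag_colmeans(as_node(Ip))
  h <- ag_relu(ag_affine(pooled, meta$W1, meta$b1))
  ag_affine(h, meta$W2, meta$b2)
}

#' Compute the image-conditioned token
#'
#' Global-average-pools the projected feature map and passes the pooled
#' vector through the non-linear fully connected meta-network `g`, yielding
#' the conditional token alpha that shifts every context vector.
#'
#' @param I_p projected feature map: H x W x D array or (H*W) x D matrix.
#' @param ctx a [prompt_context()].
#' @return 1 x e numeric matrix (alpha).
#' @export
compute_conditional_token <- function(I_p, ctx) {
  stopifnot(inherits(ctx, "prompt_context"))
  Ip <- .as_cell_matrix(I_p)
  if (any(!is.finite(Ip))) stop("projected features must be finite")
  if (ncol(Ip) != ctx$D) stop("feature width does not match the prompt context")
  ag_value(ag_conditional_token(ag_const(Ip), lapply(ctx$meta_net, ag_const)))
}

# H x W x D array -> (H*W) x D matrix, row-major over cells (row i, col j)
.as_cell_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) != 3L) stop("expected a matrix or an H x W x D array")
  out <- matrix(0, d[1L] * d[2L], d[3L])
  for (ch in seq_len(d[3L])) out[, ch] <- as.numeric(t(x[, , ch]))
  out
}

.cells_to_array <- function(m, H, W) {
  a <- array(0, dim = c(H, W, ncol(m)))
  for (ch in seq_len(ncol(m))) a[, , ch] <- matrix(m[, ch], H, W, byrow = TRUE)
  a
}

#' Assemble dynamic conditional prompt sequences
#'
#' For each keypoint sentence, prepends the q conditional tokens
#' `V_i + alpha` (identical across keypoints of one image, since alpha is
#' computed once per image) to the embedded sentence tokens.
#'
#' @param ctx a [prompt_context()].
#' @param alpha 1 x e conditional token (e.g. from
#'   [compute_conditional_token()]); use zeros for static prompts.
#' @param sentences character vector of M keypoint sentences.
#' @param embedder function(sentence) returning a T x e token-embedding
#'   matrix.
#' @return list of M `prompt_sequence` objects: list(tokens, keypoint_index,
#'   q).
#' @export
assemble_dynamic_prompts <- function(ctx, alpha, sentences, embedder) {
  stopifnot(inherits(ctx, "prompt_context"))
  alpha <- matrix(as.numeric(alpha), 1L)
  if (ncol(alpha) != ctx$e) stop("alpha width does not match the embedding width")
  cond <- sweep(ctx$context_vectors, 2L, as.numeric(alpha), "+")
  lapply(seq_along(sentences), function(m) {
    emb <- embedder(sentences[m])
    if (!is.matrix(emb) || ncol(emb) != ctx$e)
      stop("embedder must return a T x e matrix matching the embedding width")
    structure(list(tokens = rbind(cond, emb), keypoint_index = m, q = ctx$q),
              class = "prompt_sequence")
  })
}
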