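# Tiny text and image encoders, the shared-width projection, residual
# attention over keypoint prompt embeddings, and keypoint-local feature
# sampling.
#
# Both encoders are small pre-norm transformers written on the autodiff tape:
# the image encoder embeds non-overlapping patches into a grid of tokens, the
# text encoder runs all M prompt sequences jointly under a block-diagonal
# attention mask (tokens attend only within their own sequence) and pools
# each sequence at its final token. Nothing here tries to reproduce any
# pretrained model's numerics; the encoders exist so the whole pipeline is
# trainable and testable at desk scale.

# ---- tokenizer -------------------------------------------------------------

#' Build a whitespace tokenizer vocabulary
#'
#' Lowercases, strips punctuation and splits on whitespace; index 1 is the
#' `<unk>` token for out-of-vocabulary words.
#'
#' @param texts character vector to harvest words from.
#' @return character vector vocabulary.
#' @export
make_vocab <- function(texts) {
  words <- unlist(strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(texts))), "\\s+"))
  words <- words[nzchar(words)]
  c("<unk>", sort(unique(words)))
}

#' Tokenize a sentence to vocabulary ids
#'
#' @param text a sentence.
#' @param vocab vocabulary from [make_vocab()].
#' @return integer vector of token ids (unknown words map to 1).
#' @export
tokenize <- function(text, vocab) {
  words <- unlist(strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(text))), "\\s+"))
  words <- words[nzchar(words)]
  idx <- match(words, vocab)
  idx[is.na(idx)] <- 1L
  idx
}

# ---- parameter construction ------------------------------------------------

.init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

.init_block <- function(width, hidden = 2L * width, sd = 0.02) {
  list(ln1_g = matrix(1, 1L, width), ln1_b = matrix(0, 1L, width),
       Wq = .init_mat(width, width, sd), bq = matrix(0, 1L, width),
       Wk = .init_mat(width, width, sd), bk = matrix(0, 1L, width),
       Wv = .init_mat(width, width, sd), bv = matrix(0, 1L, width),
       Wo = .init_mat(width, width, sd), bo = matrix(0, 1L, width),
       ln2_g = matrix(1, 1L, width), ln2_b = matrix(0, 1L, width),
       W1 = .init_mat(width, hidden, sd), b1 = matrix(0, 1L, hidden),
       W2 = .init_mat(hidden, width, sd), b2 = matrix(0, 1L, width))
}

#' Create a tiny image encoder
#'
#' A patch-embedding vision transformer: the image is cut into
#' non-overlapping `patch_size` squares, each embedded by one affine map,
#' given learned positional embeddings and passed through `n_blocks`
#' single-head pre-norm transformer blocks. With `n_blocks = 0` it reduces
#' to a pure patch embedding.
#'
#' @param input_size input image side in px.
#' @param patch_size patch side in px (must divide `input_size`).
#' @param width output channel count D_I.
#' @param n_blocks number of transformer blocks.
#' @param seed initialization seed.
#' @return object of class `tiny_image_encoder`.
#' @export
tiny_image_encoder <- function(input_size = 64L, patch_size = 4L, width = 32L,
                               n_blocks = 1L, seed = 1L) {
  if (input_size %% patch_size != 0L) stop("patch_size must divide input_size")
  grid <- input_size %/% patch_size
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  structure(list(
    input_size = as.integer(input_size), patch_size = as.integer(patch_size),
    grid = as.integer(grid), width = as.integer(width),
    n_blocks = as.integer(n_blocks),
    params = c(list(Wp = .init_mat(3L * patch_size^2, width),
                    bp = matrix(0, 1L, width),
                    pos = .init_mat(grid^2, width),
                    lnf_g = matrix(1, 1L, width), lnf_b = matrix(0, 1L, width)),
               if (n_blocks > 0L)
                 list(blocks = lapply(seq_len(n_blocks), function(i) .init_block(width))))),
    class = "tiny_image_encoder")
}

#' Create a tiny text encoder
#'
#' A transformer over embedded token sequences with learned positional
#' embeddings; each sequence is pooled at its final token and mapped to the
#' shared width D by one affine projection. Operates on already-embedded
#' tokens so prompt assembly can inject conditional context rows.
#'
#' @param vocab vocabulary (see [make_vocab()]); the embedding table has one
#'   row per entry.
#' @param embed_width token-embedding width e.
#' @param out_width output width D (shared with projected image features).
#' @param n_blocks number of transformer blocks.
#' @param max_len maximum sequence length (context window).
#' @param seed initialization seed.
#' @return object of class `tiny_text_encoder`.
#' @export
tiny_text_encoder <- function(vocab, embed_width = 32L, out_width = 32L,
                              n_blocks = 1L, max_len = 64L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  structure(list(
    vocab = vocab, embed_width = as.integer(embed_width),
    out_width = as.integer(out_width), n_blocks = as.integer(n_blocks),
    max_len = as.integer(max_len),
    params = c(list(embed = .init_mat(length(vocab), embed_width),
                    pos = .init_mat(max_len, embed_width),
                    lnf_g = matrix(1, 1L, embed_width),
                    lnf_b = matrix(0, 1L, embed_width),
                    Wout = .init_mat(embed_width, out_width),
                    bout = matrix(0, 1L, out_width)),
               if (n_blocks > 0L)
                 list(blocks = lapply(seq_len(n_blocks), function(i)
                   .init_block(embed_width))))),
    class = "tiny_text_encoder")
}

#' Token embedder bound to a text encoder
#'
#' @param encoder a [tiny_text_encoder()].
#' @return function(sentence) returning the T x e embedding matrix of its
#'   tokens.
#' @export
text_embedder <- function(encoder) {
  stopifnot(inherits(encoder, "tiny_text_encoder"))
  function(sentence) {
    ids <- tokenize(sentence, encoder$vocab)
    encoder$params$embed[ids, , drop = FALSE]
  }
}

# ---- graph-space forward pieces -------------------------------------------

# single-head pre-norm transformer block; `lengths` restricts attention to
# consecutive row blocks (one per sequence), NULL means full attention
ag_transformer_block <- function(X, blk, lengths = NULL) {
  Xn <- ag_layernorm_rows(X, blk$ln1_g, blk$ln1_b)
  Qm <- ag_affine(Xn, blk$Wq, blk$bq)
  Km <- ag_affine(Xn, blk$Wk, blk$bk)
  Vm <- ag_affine(Xn, blk$Wv, blk$bv)
  dk <- ncol(ag_value(Qm))
  att <- ag_affine(ag_sdp_attention(Qm, Km, Vm, lengths, 1 / sqrt(dk)),
                   blk$Wo, blk$bo)
  X2 <- ag_add(X, att)
  Xn2 <- ag_layernorm_rows(X2, blk$ln2_g, blk$ln2_b)
  h <- ag_relu(ag_affine(Xn2, blk$W1, blk$b1))
  ag_add(X2, ag_affine(h, blk$W2, blk$b2))
}

# image tokens from a precomputed patch matrix (G^2 x 3p^2 constant)
ag_image_tokens <- function(patches, p) {
  X <- ag_affine(as_node(patches), p$Wp, p$bp)
  X <- ag_add(X, as_node(p$pos))
  if (!is.null(p$blocks)) for (blk in p$blocks) X <- ag_transformer_block(X, blk)
  ag_layernorm_rows(X, p$lnf_g, p$lnf_b)
}

# run concatenated prompt sequences through the text transformer.
# tokens: node of stacked rows; lengths: per-sequence row counts. Attention
# is block-diagonal: tokens attend only within their own sequence.
ag_text_forward <- function(tokens, lengths, p) {
  posidx <- unlist(lapply(lengths, seq_len))
  X <- ag_add(tokens, ag_gather_rows(as_node(p$pos), posidx))
  if (!is.null(p$blocks)) for (blk in p$blocks) X <- ag_transformer_block(X, blk, lengths)
  X <- ag_layernorm_rows(X, p$lnf_g, p$lnf_b)
  last <- cumsum(lengths)
  ag_affine(ag_gather_rows(X, last), p$Wout, p$bout)
}

# ---- public encoding operations -------------------------------------------

# extract non-overlapping patches as a (grid^2) x (3 * p^2) matrix,
# cells in row-major order
.patchify <- function(image, patch_size) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  g_h <- H %/% patch_size; g_w <- W %/% patch_size
  out <- matrix(0, g_h * g_w, 3L * patch_size^2)
  r <- 0L
  for (i in seq_len(g_h)) for (j in seq_len(g_w)) {
    r <- r + 1L
    rows <- ((i - 1L) * patch_size + 1L):(i * patch_size)
    cols <- ((j - 1L) * patch_size + 1L):(j * patch_size)
    out[r, ] <- as.numeric(image[rows, cols, ])
  }
  out
}

#' Encode an image to a spatial feature map
#'
#' @param image input_size x input_size x 3 array in [0, 1].
#' @param encoder a [tiny_image_encoder()].
#' @return H x W x D_I feature-map array (H = W = input_size / patch_size).
#' @export
encode_image <- function(image, encoder) {
  stopifnot(inherits(encoder, "tiny_image_encoder"))
  d <- dim(image)
  if (length(d) != 3L || d[1L] != encoder$input_size || d[2L] != encoder$input_size)
    stop(sprintf("image must be %dx%dx3 for this encoder",
                 encoder$input_size, encoder$input_size))
  tok <- ag_value(ag_image_tokens(.patchify(image, encoder$patch_size),
                                  lapply_nodes(encoder$params)))
  .cells_to_array(tok, encoder$grid, encoder$grid)
}

# wrap every matrix leaf of a nested parameter list as a constant node
lapply_nodes <- function(x) {
  if (is.matrix(x)) return(ag_const(x))
  if (is.list(x)) return(lapply(x, lapply_nodes))
  x
}

#' Project image features to the shared width
#'
#' Applies one affine map per grid cell, aligning the image feature width
#' D_I with the text feature width D.
#'
#' @param I feature map (H x W x D_I array or cell matrix).
#' @param projection list with `W` (D_I x D) and `b` (length-D bias).
#' @return H x W x D array (or cell matrix if `I` was one).
#' @export
project_image_features <- function(I, projection) {
  W <- projection$W; b <- matrix(as.numeric(projection$b), 1L)
  was_mat <- is.matrix(I)
  m <- .as_cell_matrix(I)
  if (ncol(m) != nrow(W)) stop("projection width does not match feature width")
  out <- sweep(m %*% W, 2L, as.numeric(b), "+")
  if (was_mat) out else .cells_to_array(out, dim(I)[1L], dim(I)[2L])
}

#' Encode prompt sequences to keypoint text embeddings
#'
#' Runs the M prompt sequences through the text encoder (jointly, under a
#' block-diagonal attention mask), pools each at its final token and projects
#' to the shared width D.
#'
#' @param seqs list of `prompt_sequence` objects from
#'   [assemble_dynamic_prompts()].
#' @param encoder a [tiny_text_encoder()].
#' @return M x D matrix of raw prompt embeddings P_raw.
#' @export
encode_prompts <- function(seqs, encoder) {
  stopifnot(inherits(encoder, "tiny_text_encoder"))
  lengths <- vapply(seqs, function(s) nrow(s$tokens), integer(1L))
  if (any(lengths > encoder$max_len))
    stop("prompt sequence exceeds the encoder context window (", encoder$max_len, ")")
  tokens <- do.call(rbind, lapply(seqs, function(s) s$tokens))
  ag_value(ag_text_forward(ag_const(tokens), lengths, lapply_nodes(encoder$params)))
}

# graph-space residual attention; returns list(node, weights)
ag_residual_attention <- function(P, pars) {
  Qm <- ag_affine(P, pars$Wq, pars$bq)
  Km <- ag_affine(P, pars$Wk, pars$bk)
  Vm <- ag_affine(P, pars$Wv, pars$bv)
  dk <- ncol(ag_value(Qm))
  A <- ag_softmax_rows(ag_scale(ag_matmul(Qm, ag_t(Km)), 1 / sqrt(dk)))
  list(node = ag_add(P, ag_matmul(A, Vm)), weights = ag_value(A))
}

#' Initialize residual-attention parameters
#'
#' @param D feature width.
#' @param seed initialization seed.
#' @param value_sd init scale of the value projection (0 makes the module an
#'   exact identity, useful for ablations and tests).
#' @return parameter list (Wq, bq, Wk, bk, Wv, bv).
#' @export
residual_attention_params <- function(D, seed = 1L, value_sd = 0.02) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  list(Wq = .init_mat(D, D), bq = matrix(0, 1L, D),
       Wk = .init_mat(D, D), bk = matrix(0, 1L, D),
       Wv = .init_mat(D, D, value_sd), bv = matrix(0, 1L, D))
}

#' Residual attention over keypoint prompt embeddings
#'
#' Single-head self-attention across the M keypoint rows, added back to the
#' input: `P_prompt = P_raw + Attn(P_raw)`. Models semantic relations
#' between keypoints (e.g. nose and eyes inform each other). The attention
#' weight matrix (rows non-negative, summing to 1) is attached as attribute
#' `"weights"`.
#'
#' @param P_raw M x D matrix of prompt embeddings.
#' @param pars parameters from [residual_attention_params()].
#' @return M x D matrix P_prompt with attribute `"weights"`.
#' @export
residual_attention <- function(P_raw, pars) {
  out <- ag_residual_attention(ag_const(P_raw), lapply_nodes(pars))
  structure(ag_value(out$node), weights = out$weights)
}

# ---- keypoint-local sampling ----------------------------------------------

# bilinear sampling-weight matrix: rows = keypoints, cols = grid cells.
# Keypoint px coords are mapped to feature-cell coordinates by
# cell = px / patch_size - 0.5 (cell (i, j) has center ((j+0.5) p, (i+0.5) p)
# image px); a k x k grid with spacing `stride` cells is averaged; sample
# points beyond the border are clamped.
.sampling_weights <- function(keypoints_px, grid_h, grid_w, patch_size,
                              k = 3L, stride = 1) {
  M <- nrow(keypoints_px)
  Wm <- matrix(0, M, grid_h * grid_w)
  offs <- (seq_len(k) - (k + 1) / 2) * stride
  for (m in seq_len(M)) {
    cx <- keypoints_px[m, 1L] / patch_size - 0.5
    cy <- keypoints_px[m, 2L] / patch_size - 0.5
    for (oy in offs) for (ox in offs) {
      sx <- min(max(cx + ox, 0), grid_w - 1)
      sy <- min(max(cy + oy, 0), grid_h - 1)
      x0 <- min(floor(sx), grid_w - 2); y0 <- min(floor(sy), grid_h - 2)
      if (grid_w == 1L) x0 <- 0L
      if (grid_h == 1L) y0 <- 0L
      fx <- sx - x0; fy <- sy - y0
      for (dd in list(c(0, 0, (1 - fy) * (1 - fx)), c(0, 1, (1 - fy) * fx),
                      c(1, 0, fy * (1 - fx)), c(1, 1, fy * fx))) {
        yy <- y0 + dd[1L]; xx <- x0 + dd[2L]
        if (yy >= grid_h || xx >= grid_w || dd[3L] == 0) next
        col <- yy * grid_w + xx + 1L
        Wm[m, col] <- Wm[m, col] + dd[3L] / k^2
      }
    }
  }
  Wm
}

#' Sample keypoint-local image features
#'
#' For each keypoint, bilinearly samples the projected feature map on a
#' k x k grid centered at the keypoint with fixed spacing `stride` (in
#' feature cells) and averages the samples to one D-vector. Sample points
#' outside the map are clamped to the border.
#'
#' @param I_p projected feature map (H x W x D array or cell matrix with
#'   attribute dims).
#' @param keypoints M x 3 matrix (x px, y px, v) in encoder-input pixels.
#' @param patch_size image px per feature cell.
#' @param k grid side (default 3).
#' @param stride grid spacing in feature cells (default 1).
#' @return M x D matrix I_keypoint.
#' @export
sample_keypoint_features <- function(I_p, keypoints, patch_size, k = 3L, stride = 1) {
  keypoints <- matrix(as.numeric(keypoints), ncol = 3L)
  bad <- keypoints[, 3L] > 0 & (!is.finite(keypoints[, 1L]) | !is.finite(keypoints[, 2L]))
  if (any(bad)) stop("labeled keypoints must have finite coordinates")
  d <- dim(I_p)
  if (length(d) != 3L) stop("I_p must be an H x W x D array")
  Wm <- .sampling_weights(keypoints[, 1:2, drop = FALSE], d[1L], d[2L],
                          patch_size, k, stride)
  Wm %*% .as_cell_matrix(I_p)
}
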