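# Model assembly: configuration, parameter initialization, and the single
# forward pass that wires prompt construction, encoding, contrastive
# matching, spatial similarity and the heatmap head into one training graph.

#' Model and training configuration
#'
#' Architecture defaults are the desk-scale profile (64 px inputs, width-32
#' encoders with one transformer block each); the optimization defaults are
#' the full-scale schedule (AdamW, lr 1e-4, weight decay 1e-4, batch 32, 210
#' epochs with step decays by a factor of 10 at epochs 170 and 200, beta 2,
#' context length q 8). Tests and examples override the schedule with much
#' shorter runs.
#'
#' @param input_size encoder input side in px.
#' @param patch_size patch side in px.
#' @param d_img image feature width D_I.
#' @param d_shared shared projected width D.
#' @param d_embed token-embedding width e.
#' @param n_img_blocks,n_txt_blocks transformer depth of the two encoders.
#' @param q context length (number of conditional prompt tokens).
#' @param grid_k,grid_stride keypoint-local sampling grid side and spacing
#'   (feature cells).
#' @param sigma_h target-heatmap Gaussian width in heatmap cells.
#' @param sigma_s spatial-target Gaussian width in feature cells.
#' @param head_hidden hidden width of the heatmap head.
#' @param temp_init initial softmax temperature of the matching loss (the
#'   logit scale is learnable unless `temp_learnable = FALSE`).
#' @param temp_learnable learn the matching temperature?
#' @param beta weight of the matching and spatial loss terms.
#' @param lr,weight_decay,batch_size,epochs AdamW schedule parameters.
#' @param lr_decay_epochs epochs after which the learning rate is divided by
#'   `lr_decay_factor` (strictly increasing, less than `epochs`).
#' @param lr_decay_factor step-decay divisor.
#' @param max_steps optional cap on total optimizer steps (NULL = none);
#'   used by the short desk-scale runs.
#' @param seed global seed covering weight init, template draw and shuffling.
#' @param templates a [template_set()].
#' @param use_ls,use_lq,use_attention,use_tp,use_pq ablation switches:
#'   spatial loss, matching loss, residual attention, sentence templates
#'   (off = bare keypoint names), conditional tokens (off = static prompts,
#'   alpha forced to 0).
#' @return object of class `ppose_config`.
#' @export
ppose_config <- function(input_size = 64L, patch_size = 4L, d_img = 32L,
                         d_shared = 32L, d_embed = 32L,
                         n_img_blocks = 1L, n_txt_blocks = 1L, q = 8L,
                         grid_k = 3L, grid_stride = 1,
                         sigma_h = 2, sigma_s = 1,
                         head_hidden = 48L,
                         temp_init = 0.07, temp_learnable = TRUE,
                         beta = 2,
                         lr = 1e-4, weight_decay = 1e-4, batch_size = 32L,
                         epochs = 210L, lr_decay_epochs = c(170L, 200L),
                         lr_decay_factor = 10, max_steps = NULL,
                         seed = 1L, templates = default_template_set(),
                         use_ls = TRUE, use_lq = TRUE, use_attention = TRUE,
                         use_tp = TRUE, use_pq = TRUE) {
  if (lr <= 0) stop("lr must be positive")
  if (length(lr_decay_epochs) &&
      (is.unsorted(lr_decay_epochs, strictly = TRUE) ||
       any(lr_decay_epochs >= epochs)))
    stop("lr_decay_epochs must be strictly increasing and below epochs")
  structure(as.list(environment()), class = "ppose_config")
}

#' Learning rate at a given epoch under the step schedule
#'
#' @param cfg a [ppose_config()].
#' @param epoch 1-based epoch number.
#' @return the learning rate in force during that epoch.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr / cfg$lr_decay_factor^sum(epoch > cfg$lr_decay_epochs)
}

# wrap nested matrices as ag_param nodes and collect a named flat list
.wrap_params <- function(x, prefix = "") {
  flat <- list()
  wrap <- function(x, prefix) {
    if (is.matrix(x)) {
      n <- ag_param(x)
      flat[[prefix]] <<- n
      return(n)
    }
    if (is.list(x)) {
      out <- x
      for (nm in names(x))
        out[[nm]] <- wrap(x[[nm]], paste0(prefix, if (nzchar(prefix)) ".", nm))
      return(out)
    }
    x
  }
  nodes <- wrap(x, prefix)
  list(nodes = nodes, flat = flat)
}

.strip_params <- function(x) {
  if (inherits(x, "ag_node")) return(x$value)
  if (is.list(x)) return(lapply(x, .strip_params))
  x
}

#' Initialize a pose-estimation model
#'
#' Draws one sentence per keypoint from the template set (fixed for the life
#' of the model), builds the vocabulary, and initializes all trainable
#' parameters: both encoders, the feature projection, context vectors and
#' meta-network, residual attention, the heatmap head and the matching
#' temperature.
#'
#' @param schema a [keypoint_schema()].
#' @param config a [ppose_config()].
#' @return object of class `promptpose_model`.
#' @export
promptpose_model <- function(schema, config = ppose_config()) {
  stopifnot(inherits(schema, "keypoint_schema"), inherits(config, "ppose_config"))
  M <- schema$M
  sentences <- fill_templates(schema, config$templates, seed = config$seed)
  plain <- schema$keypoint_names
  vocab <- make_vocab(c(sentences, plain))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  img_enc <- tiny_image_encoder(config$input_size, config$patch_size,
                                config$d_img, config$n_img_blocks,
                                seed = config$seed + 2L)
  txt_enc <- tiny_text_encoder(vocab, config$d_embed, config$d_shared,
                               config$n_txt_blocks, max_len = 64L,
                               seed = config$seed + 3L)
  pctx <- prompt_context(config$q, config$d_embed, config$d_shared,
                         seed = config$seed + 4L)
  init <- list(
    img = img_enc$params,
    txt = txt_enc$params,
    proj = list(W = .init_mat(config$d_img, config$d_shared),
                b = matrix(0, 1L, config$d_shared)),
    ctx = list(V = pctx$context_vectors),
    meta = pctx$meta_net,
    attn = residual_attention_params(config$d_shared, seed = config$seed + 5L),
    head = list(W1 = .init_mat(config$d_img + M, config$head_hidden),
                b1 = matrix(0, 1L, config$head_hidden),
                W2 = .init_mat(config$head_hidden, 4L * M, 0.01),
                b2 = matrix(0, 1L, 4L * M)),
    log_temp = matrix(log(1 / config$temp_init), 1L, 1L))
  w <- .wrap_params(init)
  if (!config$temp_learnable) w$flat[["log_temp"]] <- NULL
  ids_full <- lapply(sentences, tokenize, vocab = vocab)
  ids_plain <- lapply(plain, tokenize, vocab = vocab)
  structure(list(
    schema = schema, config = config, sentences = sentences, vocab = vocab,
    img_meta = img_enc[c("input_size", "patch_size", "grid", "width", "n_blocks")],
    txt_meta = txt_enc[c("embed_width", "out_width", "n_blocks", "max_len")],
    ids_full = ids_full, ids_plain = ids_plain,
    p = w$nodes, flat = w$flat,
    head_meta = list(M = M, upsample = 2L)),
    class = "promptpose_model")
}

# ---- per-instance sample preparation --------------------------------------

# One training/eval sample: the crop patch matrix plus every ground-truth
# derived constant the loss needs. `kp` is in crop px.
.prepare_sample <- function(image, ann, model) {
  cfg <- model$config
  G <- model$img_meta$grid
  bb <- ann$bbox
  crop <- crop_resize(image, bb, cfg$input_size)
  sc <- attr(crop, "scale"); off <- attr(crop, "offset")
  kp <- ann$keypoints
  kpc <- cbind((kp[, 1L] - off[1L]) * sc[1L], (kp[, 2L] - off[2L]) * sc[2L],
               kp[, 3L])
  kpc[kp[, 3L] == 0, 1:2] <- 0
  vis <- kpc[, 3L] > 0
  hm_stride <- cfg$patch_size / 2
  ht <- make_target_heatmaps(
    cbind(kpc[, 1L] / hm_stride - 0.5, kpc[, 2L] / hm_stride - 0.5, kpc[, 3L]),
    c(2L * G, 2L * G), sigma_h = cfg$sigma_h, stride = hm_stride)
  list(patches = .patchify(crop, cfg$patch_size),
       kp = kpc, vis = vis,
       Wsamp = .sampling_weights(kpc[, 1:2, drop = FALSE], G, G,
                                 cfg$patch_size, cfg$grid_k, cfg$grid_stride),
       ht_blocks = maps_to_blocks(ht$maps, G, G),
       S_t = spatial_targets(kpc, G, G, cfg$patch_size, cfg$sigma_s),
       ann_id = ann$id, image_id = ann$image_id,
       crop_scale = sc, crop_offset = off)
}

#' Prepare per-instance samples from an annotation set
#'
#' Crops every annotated instance to the encoder input size and precomputes
#' the ground-truth constants used by the loss (target heatmaps, spatial
#' targets, keypoint sampling stencils).
#'
#' @param aset an [annotation_set()] whose images live in `dir`.
#' @param model a [promptpose_model()].
#' @param dir image directory (defaults to `attr(aset, "dir")`).
#' @return list of samples.
#' @export
prepare_samples <- function(aset, model, dir = attr(aset, "dir")) {
  stopifnot(inherits(aset, "annotation_set"))
  if (is.null(dir)) stop("no image directory: pass `dir` or use a set that carries one")
  cache <- new.env(parent = emptyenv())
  get_image <- function(id) {
    key <- as.character(id)
    if (is.null(cache[[key]])) {
      fn <- aset$images$file_name[match(id, aset$images$id)]
      img <- png::readPNG(file.path(dir, fn))
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
      cache[[key]] <- img[, , 1:3, drop = FALSE]
    }
    cache[[key]]
  }
  lapply(aset$annotations, function(a) .prepare_sample(get_image(a$image_id), a, model))
}

# ---- forward pass ----------------------------------------------------------

# Full forward graph for one sample. Returns the graph nodes needed for
# training plus a numeric loss breakdown. When `sample$vis` is absent (pure
# inference) the loss terms are skipped.
ppose_forward <- function(model, sample, with_loss = TRUE) {
  cfg <- model$config
  p <- model$p
  M <- model$schema$M
  G <- model$img_meta$grid
  I_tokens <- ag_image_tokens(sample$patches, p$img)         # G^2 x D_I
  I_p <- ag_affine(I_tokens, p$proj$W, p$proj$b)             # G^2 x D
  alpha <- if (cfg$use_pq) ag_conditional_token(I_p, p$meta)
  else ag_const(matrix(0, 1L, cfg$d_embed))
  cond <- ag_add_rowvec(p$ctx$V, alpha)                      # q x e
  ids <- if (cfg$use_tp) model$ids_full else model$ids_plain
  seqs <- lapply(seq_len(M), function(m)
    ag_rbind(cond, ag_gather_rows(p$txt$embed, ids[[m]])))
  lengths <- cfg$q + lengths(ids)
  tokens <- Reduce(ag_rbind, seqs)
  P_raw <- ag_text_forward(tokens, lengths, p$txt)           # M x D
  P_prompt <- if (cfg$use_attention)
    ag_residual_attention(P_raw, p$attn)$node else P_raw
  Pn <- ag_normalize_rows(P_prompt, eps = 1e-8)
  Ipn <- ag_normalize_rows(I_p, eps = 1e-8)
  S <- ag_matmul(Pn, ag_t(Ipn))                              # M x G^2
  blocks <- ag_heatmap_head(I_tokens, S, p$head)             # G^2 x 4M
  out <- list(I_tokens = I_tokens, I_p = I_p, alpha = alpha, P_raw = P_raw,
              P_prompt = P_prompt, S = S, blocks = blocks)
  if (!with_loss) return(out)
  vis <- sample$vis
  hm <- ag_masked_sse_mean(ag_t(blocks), t(sample$ht_blocks),
                           rep(vis, each = 4L), denom = sum(vis))
  sp <- ag_masked_sse_mean(S, sample$S_t, vis)
  Ikp <- ag_matmul(ag_const(sample$Wsamp), I_p)              # M x D
  out$I_keypoint <- Ikp
  vidx <- which(vis)
  ce <- if (cfg$use_lq && length(vidx) >= 2L) {
    Qvis <- ag_matmul(ag_gather_rows(Pn, vidx),
                      ag_t(ag_gather_rows(ag_normalize_rows(Ikp, eps = 1e-8), vidx)))
    out$Q_vis <- Qvis
    ag_matching_loss(Qvis, ag_exp(p$log_temp))
  } else NULL
  total <- hm
  if (!is.null(ce)) total <- ag_add(total, ag_scale(ce, cfg$beta))
  if (cfg$use_ls) total <- ag_add(total, ag_scale(sp, cfg$beta))
  out$total <- total
  out$breakdown <- loss_breakdown(
    ag_value(hm)[1L],
    if (!is.null(ce)) ag_value(ce)[1L] else 0,
    if (cfg$use_ls) ag_value(sp)[1L] else 0,
    cfg$beta)
  out
}

# decode one forward result to original-image keypoints
.decode_sample <- function(model, fw, sample) {
  G <- model$img_meta$grid
  maps <- blocks_to_maps(ag_value(fw$blocks), G, G, model$schema$M)
  dec <- decode_heatmaps(heatmap_set(maps, model$config$patch_size / 2))
  sc <- sample$crop_scale; off <- sample$crop_offset
  cbind(dec[, 1L] / sc[1L] + off[1L], dec[, 2L] / sc[2L] + off[2L], dec[, 3L])
}
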