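# Model fitting: AdamW with a step learning-rate schedule over per-instance
# crops, plus the classed model object with its standard methods.

# decoupled-weight-decay Adam update on the flat parameter list
.adamw_step <- function(flat, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    p <- flat[[nm]]
    g <- p$grad
    if (is.null(g)) next
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[nm]] <- m; state$v[[nm]] <- v
    p$value <- p$value - lr * wd * p$value - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  invisible(state)
}

#' Fit a prompt-based pose estimation model
#'
#' Trains every component end to end on per-instance crops: the two
#' encoders, the feature projection, the learnable prompt context and
#' meta-network, residual attention, the heatmap head and (optionally) the
#' matching temperature, under the composite loss
#' `heatmap + beta * (matching + spatial)`. Optimization is AdamW with a
#' step learning-rate schedule; one optimizer step per minibatch, gradients
#' averaged over the batch. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param data an [annotation_set()] carrying its image directory (as
#'   produced by [generate_synthetic_dataset()]), or a list of prepared
#'   samples from [prepare_samples()].
#' @param schema a [keypoint_schema()]; defaults to the data's schema.
#' @param config a [ppose_config()].
#' @param dir image directory override.
#' @param verbose print per-epoch losses?
#' @return object of class `promptpose`: the fitted model with a per-epoch
#'   loss history.
#' @seealso [predict.promptpose()], [simulate.promptpose()],
#'   [run_ablation()]
#' @export
promptpose <- function(data, schema = NULL, config = ppose_config(),
                       dir = NULL, verbose = FALSE) {
  if (inherits(data, "annotation_set")) {
    schema <- data$schema
    model <- promptpose_model(schema, config)
    samples <- prepare_samples(data, model, dir = dir %||% attr(data, "dir"))
  } else {
    if (is.null(schema)) stop("schema is required when passing prepared samples")
    model <- promptpose_model(schema, config)
    samples <- data
  }
  if (!length(samples)) stop("no training instances")
  # The tape allocates fresh matrices for every graph node and never mutates
  # in place, so training churns through memory quickly; holding one large
  # live allocation keeps R's GC trigger high and collections rare, which
  # cuts wall time substantially without changing any result.
  ballast <- raw(3e8)
  on.exit(rm(ballast), add = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 10L)
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  history <- NULL
  steps_done <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    idx <- sample(length(samples))
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    comp <- c(heatmap_mse = 0, matching_ce = 0, spatial_mse = 0, total = 0)
    nb <- 0L
    for (b in batches) {
      ag_zero_grads(model$flat)
      for (si in b) {
        fw <- ppose_forward(model, samples[[si]])
        if (!is.finite(fw$breakdown$total))
          stop(sprintf("non-finite loss at epoch %d (instance %d): %s",
                       epoch, samples[[si]]$ann_id,
                       paste(sprintf("%s=%g", names(fw$breakdown)[1:3],
                                     unlist(fw$breakdown)[1:3]), collapse = " ")))
        ag_backward(ag_scale(fw$total, 1 / length(b)))
        comp <- comp + c(fw$breakdown$heatmap_mse, fw$breakdown$matching_ce,
                         fw$breakdown$spatial_mse, fw$breakdown$total)
        nb <- nb + 1L
      }
      .adamw_step(model$flat, state, lr, config$weight_decay)
      steps_done <- steps_done + 1L
      if (!is.null(config$max_steps) && steps_done >= config$max_steps) break
    }
    comp <- comp / nb
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         heatmap_mse = comp[1L],
                                         matching_ce = comp[2L],
                                         spatial_mse = comp[3L],
                                         total = comp[4L]))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  total %.5f (hm %.5f ce %.5f sp %.5f)",
                      epoch, lr, comp[4L], comp[1L], comp[2L], comp[3L]))
    if (!is.null(config$max_steps) && steps_done >= config$max_steps) break
  }
  rownames(history) <- NULL
  model$history <- history
  model$n_train <- length(samples)
  class(model) <- c("promptpose", class(model))
  model
}

# ---- inference -------------------------------------------------------------

#' Predict keypoints for instance boxes
#'
#' Top-down inference: one prediction per (image, box). Deterministic given
#' the fitted parameters.
#'
#' @param object a fitted `promptpose` model.
#' @param newdata an [annotation_set()] (its bboxes define the instances),
#'   or a list of prepared samples.
#' @param dir image directory override.
#' @param ... unused.
#' @return list of prediction records (annotation_id, image_id, keypoints
#'   M x 3 with decode scores in column 3, score), suitable for
#'   [evaluate_dataset()] and [write_coco_results()].
#' @export
predict.promptpose <- function(object, newdata, dir = NULL, ...) {
  samples <- if (inherits(newdata, "annotation_set")) {
    if (newdata$schema$M != object$schema$M)
      stop("annotation schema does not match the fitted model")
    prepare_samples(newdata, object, dir = dir %||% attr(newdata, "dir"))
  } else newdata
  lapply(samples, function(s) {
    fw <- ppose_forward(object, s, with_loss = FALSE)
    kp <- .decode_sample(object, fw, s)
    list(annotation_id = s$ann_id, image_id = s$image_id, category_id = 1L,
         keypoints = kp, score = mean(kp[, 3L]))
  })
}

#' @export
print.promptpose <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("promptpose model: schema '%s' (M = %d), %dpx input, D_I = %d, D = %d, q = %d\n",
              x$schema$name, x$schema$M, cfg$input_size, cfg$d_img,
              cfg$d_shared, cfg$q))
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("trained %d epochs on %d instances; total loss %.4f -> %.4f\n",
                nrow(h), x$n_train, h$total[1L], h$total[nrow(h)]))
  } else cat("(untrained)\n")
  invisible(x)
}

#' @export
summary.promptpose <- function(object, ...) {
  np <- sum(vapply(object$flat, function(p) length(p$value), numeric(1L)))
  out <- list(schema = object$schema$name, M = object$schema$M,
              n_parameters = np, config = object$config,
              history = object$history,
              temperature = exp(-object$p$log_temp$value[1L]))
  class(out) <- "summary.promptpose"
  out
}

#' @export
print.summary.promptpose <- function(x, ...) {
  cat(sprintf("promptpose fit: schema '%s', %d keypoints, %d parameters\n",
              x$schema, x$M, x$n_parameters))
  cat(sprintf("matching temperature: %.4f\n", x$temperature))
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("epochs: %d; final losses: total %.5f = heatmap %.5f + %g x (ce %.5f + spatial %.5f)\n",
                nrow(h), h$total[nrow(h)], h$heatmap_mse[nrow(h)],
                x$config$beta, h$matching_ce[nrow(h)], h$spatial_mse[nrow(h)]))
  }
  invisible(x)
}

#' @export
coef.promptpose <- function(object, ...) {
  lapply(object$flat, function(p) p$value)
}

#' Training-set residuals
#'
#' Per-keypoint localization errors (predicted minus ground truth, in px of
#' the original image) over a dataset, for labeled keypoints; unlabeled ones
#' are NA.
#'
#' @param object a fitted `promptpose` model.
#' @param data an [annotation_set()] or prepared samples.
#' @param dir image directory override.
#' @param ... unused.
#' @return n_instances x M matrix of Euclidean errors in px.
#' @export
residuals.promptpose <- function(object, data, dir = NULL, ...) {
  samples <- if (inherits(data, "annotation_set"))
    prepare_samples(data, object, dir = dir %||% attr(data, "dir")) else data
  preds <- predict(object, samples)
  errs <- t(vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    # ground truth back in original px
    gx <- s$kp[, 1L] / s$crop_scale[1L] + s$crop_offset[1L]
    gy <- s$kp[, 2L] / s$crop_scale[2L] + s$crop_offset[2L]
    e <- sqrt((preds[[i]]$keypoints[, 1L] - gx)^2 +
                (preds[[i]]$keypoints[, 2L] - gy)^2)
    e[!s$vis] <- NA_real_
    e
  }, numeric(object$schema$M)))
  colnames(errs) <- object$schema$keypoint_names
  errs
}

#' Simulate a synthetic dataset matching the model's schema
#'
#' @param object a `promptpose` model.
#' @param nsim number of images.
#' @param seed generator seed.
#' @param cfg a [synth_config()] (its n_images/seed are overridden by
#'   `nsim`/`seed`).
#' @param dir output directory.
#' @param ... unused.
#' @return the generated [annotation_set()].
#' @export
simulate.promptpose <- function(object, nsim = 16L, seed = 1L,
                                cfg = synth_config(), dir = tempfile("sim"), ...) {
  cfg$n_images <- as.integer(nsim)
  cfg$seed <- as.integer(seed)
  generate_synthetic_dataset(cfg, object$schema, dir)
}

#' Plot the training loss curve or a skeleton overlay
#'
#' @param x a fitted `promptpose` model.
#' @param type "loss" for the per-epoch loss curves; "overlay" to draw
#'   predicted keypoints on an instance crop.
#' @param sample a prepared sample (required for `type = "overlay"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.promptpose <- function(x, type = c("loss", "overlay"), sample = NULL, ...) {
  type <- match.arg(type)
  if (type == "loss") {
    if (is.null(x$history)) stop("model has no training history")
    h <- x$history
    graphics::matplot(h$epoch, cbind(h$total, h$heatmap_mse, h$matching_ce,
                                     h$spatial_mse),
                      type = "l", lty = 1, xlab = "epoch", ylab = "loss", ...)
    graphics::legend("topright", c("total", "heatmap", "matching", "spatial"),
                     col = 1:4, lty = 1, bty = "n")
  } else {
    if (is.null(sample)) stop("overlay plot needs a prepared sample")
    fw <- ppose_forward(x, sample, with_loss = FALSE)
    G <- x$img_meta$grid
    maps <- blocks_to_maps(ag_value(fw$blocks), G, G, x$schema$M)
    dec <- decode_heatmaps(heatmap_set(maps, x$config$patch_size / 2))
    img <- .cells_to_array(matrix(0.2, x$config$input_size^2, 3L),
                           x$config$input_size, x$config$input_size)
    ov <- render_skeleton_overlay(img, cbind(dec[, 1:2], 2), x$schema)
    graphics::plot(grDevices::as.raster(ov))
  }
  invisible(x)
}

# ---- checkpointing ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Serializes configuration, schema, sentences, vocabulary and the exact
#' parameter values; [load_checkpoint()] restores a model whose inference is
#' bit-identical.
#'
#' @param model a `promptpose` (fitted or not) model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(format = "promptpose-checkpoint-1",
             schema = model$schema, config = model$config,
             sentences = model$sentences, vocab = model$vocab,
             params = .strip_params(model$p),
             history = model$history, n_train = model$n_train)
  saveRDS(ck, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return a `promptpose` model with the stored parameter values.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "promptpose-checkpoint-1"))
    stop("not a promptpose checkpoint: ", path)
  model <- promptpose_model(ck$schema, ck$config)
  stopifnot(identical(model$sentences, ck$sentences),
            identical(model$vocab, ck$vocab))
  restore <- function(nodes, vals) {
    for (nm in names(nodes)) {
      if (inherits(nodes[[nm]], "ag_node")) nodes[[nm]]$value <- vals[[nm]]
      else if (is.list(nodes[[nm]])) restore(nodes[[nm]], vals[[nm]])
    }
  }
  restore(model$p, ck$params)
  model$history <- ck$history
  model$n_train <- ck$n_train
  class(model) <- c("promptpose", class(model))
  model
}

# ---- ablation --------------------------------------------------------------

#' Run an ablation study over module switches
#'
#' Trains and evaluates one scaled-down variant per requested flag
#' combination on the same dataset, reproducing the ablation axes of the
#' method: spatial loss (LS), matching loss (LQ), residual attention (A),
#' sentence templates (Tp) and conditional tokens (Pq).
#'
#' @param data an [annotation_set()] with images.
#' @param config base [ppose_config()].
#' @param variants named list of flag lists, e.g.
#'   `list(baseline = list(use_ls = FALSE, use_lq = FALSE, ...), full = list())`.
#' @param eval_data dataset to evaluate on (default: the training data).
#' @param dir image directory override.
#' @return data.frame with one row per variant: AP, AP50, AP75, APM, APL, AR.
#' @export
run_ablation <- function(data, config = ppose_config(),
                         variants = list(
                           baseline = list(use_ls = FALSE, use_lq = FALSE,
                                           use_attention = FALSE, use_tp = FALSE,
                                           use_pq = FALSE),
                           "+LS" = list(use_lq = FALSE, use_attention = FALSE,
                                        use_tp = FALSE, use_pq = FALSE),
                           "+LS+LQ" = list(use_attention = FALSE,
                                           use_tp = FALSE, use_pq = FALSE),
                           full = list()),
                         eval_data = data, dir = NULL) {
  rows <- lapply(names(variants), function(vn) {
    cfg <- config
    for (nm in names(variants[[vn]])) cfg[[nm]] <- variants[[vn]][[nm]]
    fit <- promptpose(data, config = cfg, dir = dir)
    mr <- evaluate_dataset(predict(fit, eval_data, dir = dir), eval_data)
    data.frame(variant = vn, AP = mr$AP, AP50 = mr$AP50, AP75 = mr$AP75,
               APM = mr$APM, APL = mr$APL, AR = mr$AR)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
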