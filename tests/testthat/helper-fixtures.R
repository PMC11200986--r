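# Shared fixtures: tiny deterministic datasets and configs used across tests.

# a minimal 2-keypoint schema for hand-computable cases
toy_schema <- function() {
  keypoint_schema("toy", c("nose", "tail base"), rbind(c(0L, 1L)), sigmas = 0.1)
}

# small synthetic dataset cached per test run
fixture_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_images = 8L, image_size = 64L, seed = 7L, occlusion_rate = 0,
           schema = load_keypoint_schema("ap10k")) {
    key <- paste(n_images, image_size, seed, occlusion_rate, schema$name, sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- synth_config(n_images = n_images, image_size = image_size,
                          instances_per_image = 1L,
                          scale_mix = c(medium = 1, large = 0),
                          occlusion_rate = occlusion_rate, seed = seed)
      cache[[key]] <- generate_synthetic_dataset(
        cfg, schema, dir = file.path(tempdir(), paste0("fix_", key)))
    }
    cache[[key]]
  }
})

# short-schedule config for desk-scale training tests
short_config <- function(...) {
  args <- list(epochs = 12L, batch_size = 4L, lr = 3e-3,
               lr_decay_epochs = integer(0), max_steps = 200L, seed = 1L)
  user <- list(...)
  args[names(user)] <- user
  do.call(ppose_config, args)
}

# brute-force OKS/AP oracle: loops instances x thresholds naively
oracle_metrics <- function(oks, areas, thresholds = oks_thresholds()) {
  frac <- function(keep) {
    if (!any(keep)) return(NaN)
    mean(vapply(thresholds, function(T) 100 * mean(oks[keep] > T), numeric(1L)))
  }
  cls <- vapply(areas, function(a)
    if (a > 96^2) "large" else if (a >= 32^2) "medium" else "small", character(1L))
  list(AP = frac(rep(TRUE, length(oks))),
       AP50 = 100 * mean(oks > 0.5), AP75 = 100 * mean(oks > 0.75),
       APM = frac(cls == "medium"), APL = frac(cls == "large"),
       AR = frac(rep(TRUE, length(oks))))
}
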