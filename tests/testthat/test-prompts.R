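# Template filling, the conditional token, and dynamic prompt assembly.

test_that("template sets validate their slots", {
  expect_error(template_set(character(0), "a {kp} b", "{kp} c"), "empty")
  expect_error(template_set("no slot here", "a {kp} b", "{kp} c"), "exactly one")
  expect_error(template_set("{kp} and {kp}", "a {kp} b", "{kp} c"), "exactly one")
  tset <- default_template_set()
  expect_length(tset$prefix, 3L)
  expect_length(tset$intermediate, 3L)
  expect_length(tset$suffix, 3L)
})

test_that("template filling is seeded, verbatim and uniform", {
  sc <- load_keypoint_schema("ap10k")
  single <- template_set("a photo of the {kp}", "see the {kp} here", "{kp} shown")
  # single template set: deterministic sentence
  one <- template_set("a photo of the {kp}", "a photo of the {kp}",
                      "a photo of the {kp}")
  s <- fill_templates(sc, one, seed = 3)
  expect_equal(s[3], "a photo of the nose")
  # seed determinism
  tset <- default_template_set()
  expect_identical(fill_templates(sc, tset, seed = 5),
                   fill_templates(sc, tset, seed = 5))
  # every sentence contains its keypoint name verbatim
  s2 <- fill_templates(sc, tset, seed = 6)
  for (m in seq_len(sc$M)) expect_match(s2[m], sc$keypoint_names[m], fixed = TRUE)
  # uniformity over the pooled templates: 10^4 draws over 9 templates
  big <- keypoint_schema("big", sprintf("kp%05d", 1:10000))
  s3 <- fill_templates(big, tset, seed = 7)
  pool <- c(tset$prefix, tset$intermediate, tset$suffix)
  counts <- vapply(seq_along(pool), function(i)
    sum(startsWith(s3, substr(pool[i], 1, regexpr("{kp}", pool[i], fixed = TRUE) - 1)) &
          endsWith(s3, substr(pool[i], regexpr("{kp}", pool[i], fixed = TRUE) + 4,
                              nchar(pool[i])))), numeric(1))
  # templates are distinguishable by their fixed text; counts within 5 s.e.
  p0 <- 1 / length(pool)
  se <- sqrt(p0 * (1 - p0) * 10000)
  expect_true(all(abs(counts - 10000 * p0) <= 5 * se))
  expect_equal(sum(counts), 10000)
})

test_that("template sets load from YAML", {
  path <- system.file("extdata", "templates_default.yaml", package = "promptpose")
  tset <- read_template_set(path)
  expect_s3_class(tset, "template_set")
  expect_identical(unclass(tset), unclass(default_template_set()))
})

test_that("the conditional token is the meta-net applied to pooled features", {
  ctx <- prompt_context(q = 4L, e = 6L, D = 8L, hidden = 5L, seed = 2L)
  set.seed(12)
  Ip <- array(rnorm(3 * 3 * 8), dim = c(3, 3, 8))
  a <- compute_conditional_token(Ip, ctx)
  # independent matrix-arithmetic recomputation
  pool <- colMeans(apply(Ip, 3, as.numeric))
  h <- pmax(0, pool %*% ctx$meta_net$W1 + as.numeric(ctx$meta_net$b1))
  expect_equal(as.numeric(a),
               as.numeric(h %*% ctx$meta_net$W2 + as.numeric(ctx$meta_net$b2)),
               tolerance = 1e-12)
  # zero meta-net -> alpha = 0
  ctx0 <- ctx
  ctx0$meta_net <- lapply(ctx$meta_net, function(m) m * 0)
  expect_equal(as.numeric(compute_conditional_token(Ip, ctx0)), rep(0, 6))
  # constant feature map pools to the constant
  Ipc <- array(rep(seq_len(8), each = 9), dim = c(3, 3, 8))
  expect_equal(as.numeric(compute_conditional_token(Ipc, ctx)),
               as.numeric(pmax(0, seq_len(8) %*% ctx$meta_net$W1 +
                                 as.numeric(ctx$meta_net$b1)) %*% ctx$meta_net$W2 +
                            as.numeric(ctx$meta_net$b2)))
  expect_error(compute_conditional_token(Ip * NA, ctx), "finite")
})

test_that("dynamic prompts shift context rows by alpha and share it across keypoints", {
  sc <- toy_schema()
  ctx <- prompt_context(q = 3L, e = 4L, D = 4L, seed = 8L)
  emb <- function(sentence) matrix(seq_len(4 * 2) / 10, 2, 4)  # 2 tokens
  sents <- c("nose here", "tail there")
  a0 <- matrix(0, 1, 4)
  a1 <- matrix(c(1, -1, 0.5, 2), 1, 4)
  p0 <- assemble_dynamic_prompts(ctx, a0, sents, emb)
  p1 <- assemble_dynamic_prompts(ctx, a1, sents, emb)
  # alpha = 0 reduces to the static context vectors
  expect_equal(p0[[1]]$tokens[1:3, ], ctx$context_vectors)
  # sequence length q + T
  expect_equal(nrow(p0[[1]]$tokens), 3L + 2L)
  # conditional rows shift exactly by alpha; template rows unchanged
  d <- p1[[1]]$tokens - p0[[1]]$tokens
  expect_equal(d[1:3, ], matrix(rep(as.numeric(a1), each = 3), 3, 4))
  expect_equal(d[4:5, ], matrix(0, 2, 4))
  # identical conditional rows across keypoints of one image
  expect_equal(p1[[1]]$tokens[1:3, ], p1[[2]]$tokens[1:3, ])
  # linearity of the conditional shift
  a2 <- matrix(c(0.2, 0.1, -0.4, 0.3), 1, 4)
  p12 <- assemble_dynamic_prompts(ctx, a1 + a2, sents, emb)
  pa1 <- assemble_dynamic_prompts(ctx, a1, sents, emb)
  dd <- p12[[1]]$tokens - pa1[[1]]$tokens
  expect_equal(dd[1:3, ], matrix(rep(as.numeric(a2), each = 3), 3, 4))
  expect_equal(max(abs(dd[4:5, ])), 0)
})

test_that("prompt assembly is permutation-equivariant in keypoint order", {
  ctx <- prompt_context(q = 2L, e = 3L, D = 3L, seed = 9L)
  emb <- function(sentence) matrix(utf8ToInt(substr(sentence, 1, 1)) / 100 +
                                     seq_len(6) / 10, 2, 3)
  sents <- c("alpha point", "beta point", "gamma point")
  a <- matrix(c(0.1, 0.2, 0.3), 1, 3)
  ps <- assemble_dynamic_prompts(ctx, a, sents, emb)
  perm <- c(3, 1, 2)
  pp <- assemble_dynamic_prompts(ctx, a, sents[perm], emb)
  for (i in seq_along(perm))
    expect_equal(pp[[i]]$tokens, ps[[perm[i]]]$tokens)
})
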