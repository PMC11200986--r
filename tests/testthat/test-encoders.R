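# Encoding contracts: determinism, shapes, projection, residual attention,
# and keypoint-local sampling against a brute-force oracle.

test_that("image encoding is deterministic with config-derived shapes", {
  enc <- tiny_image_encoder(input_size = 32L, patch_size = 4L, width = 16L,
                            n_blocks = 2L, seed = 5L)
  set.seed(1)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  I1 <- encode_image(img, enc)
  I2 <- encode_image(img, enc)
  expect_identical(I1, I2)
  expect_equal(dim(I1), c(32L / 4L, 32L / 4L, 16L))
  expect_error(encode_image(array(0, dim = c(16, 16, 3)), enc), "32x32")
})

test_that("a block-free encoder maps constant images to constant maps", {
  enc <- tiny_image_encoder(input_size = 16L, patch_size = 4L, width = 8L,
                            n_blocks = 0L, seed = 2L)
  enc$params$pos[] <- 0   # positional embeddings off: pure patch embedding
  img <- array(0.37, dim = c(16, 16, 3))
  I <- encode_image(img, enc)
  for (ch in seq_len(8))
    expect_lt(diff(range(I[, , ch])), 1e-12)
})

test_that("feature projection is an exact per-cell affine map", {
  set.seed(6)
  I <- array(rnorm(4 * 4 * 6), dim = c(4, 4, 6))
  # identity projection
  idp <- list(W = diag(6), b = rep(0, 6))
  expect_equal(project_image_features(I, idp), I)
  # zero weights -> bias everywhere
  zp <- list(W = matrix(0, 6, 3), b = c(1, 2, 3))
  Ip <- project_image_features(I, zp)
  expect_equal(as.numeric(Ip[2, 3, ]), c(1, 2, 3))
  # random weights match direct per-cell multiplication
  W <- matrix(rnorm(18), 6, 3); b <- rnorm(3)
  Ip2 <- project_image_features(I, list(W = W, b = b))
  for (i in 1:4) for (j in 1:4)
    expect_equal(as.numeric(Ip2[i, j, ]), as.numeric(I[i, j, ] %*% W + b),
                 tolerance = 1e-12)
  expect_error(project_image_features(I, list(W = matrix(0, 5, 3), b = rep(0, 3))),
               "width")
})

test_that("prompt encoding produces one row per keypoint, equivariantly", {
  sc <- load_keypoint_schema("ap10k")
  tset <- default_template_set()
  sents <- fill_templates(sc, tset, seed = 2)
  enc <- tiny_text_encoder(make_vocab(sents), embed_width = 12L, out_width = 10L,
                           n_blocks = 1L, seed = 3L)
  ctx <- prompt_context(q = 4L, e = 12L, D = 10L, seed = 4L)
  seqs <- assemble_dynamic_prompts(ctx, matrix(0.1, 1, 12), sents,
                                   text_embedder(enc))
  P <- encode_prompts(seqs, enc)
  expect_equal(dim(P), c(17L, 10L))
  # identical sequences give identical rows
  seqs2 <- seqs; seqs2[[2]] <- seqs[[1]]
  P2 <- encode_prompts(seqs2, enc)
  expect_equal(P2[1, ], P2[2, ])
  # permutation equivariance
  perm <- sample(17)
  Pp <- encode_prompts(seqs[perm], enc)
  expect_equal(Pp, P[perm, ], tolerance = 1e-12)
  # context window enforcement
  long <- seqs
  long[[1]]$tokens <- matrix(0, 100, 12)
  expect_error(encode_prompts(long, enc), "context window")
})

test_that("residual attention is a residual softmax update", {
  set.seed(7)
  M <- 5L; D <- 8L
  P <- matrix(rnorm(M * D), M, D)
  pars <- residual_attention_params(D, seed = 8L)
  out <- residual_attention(P, pars)
  W <- attr(out, "weights")
  expect_equal(dim(W), c(M, M))
  expect_true(all(W >= 0))
  expect_equal(rowSums(W), rep(1, M), tolerance = 1e-6)
  expect_equal(dim(out), dim(P))
  # zero value projection -> exact identity
  pars0 <- residual_attention_params(D, seed = 8L, value_sd = 0)
  pars0$bv[] <- 0
  expect_equal(unclass(residual_attention(P, pars0))[1:M, ], P)
  # M = 1: weight exactly 1, output = P + value(P)
  P1 <- P[1, , drop = FALSE]
  o1 <- residual_attention(P1, pars)
  expect_equal(as.numeric(attr(o1, "weights")), 1)
  expect_equal(as.numeric(o1), as.numeric(P1 + (P1 %*% pars$Wv + as.numeric(pars$bv))))
})

test_that("keypoint sampling matches a brute-force bilinear oracle", {
  set.seed(9)
  G <- 8L; D <- 5L; p <- 4L
  Ip <- array(rnorm(G * G * D), dim = c(G, G, D))
  bilinear <- function(cx, cy) {
    cx <- min(max(cx, 0), G - 1); cy <- min(max(cy, 0), G - 1)
    x0 <- min(floor(cx), G - 2); y0 <- min(floor(cy), G - 2)
    fx <- cx - x0; fy <- cy - y0
    (1 - fy) * ((1 - fx) * Ip[y0 + 1, x0 + 1, ] + fx * Ip[y0 + 1, x0 + 2, ]) +
      fy * ((1 - fx) * Ip[y0 + 2, x0 + 1, ] + fx * Ip[y0 + 2, x0 + 2, ])
  }
  # k = 1 at an exact cell center returns that cell's vector
  kp <- cbind((3 + 0.5) * p, (2 + 0.5) * p, 2)   # cell (row 2, col 3)
  f <- sample_keypoint_features(Ip, kp, p, k = 1L)
  expect_equal(as.numeric(f), as.numeric(Ip[3, 4, ]), tolerance = 1e-12)
  # constant map returns the constant for any grid
  Ipc <- array(rep(1:D, each = G * G), dim = c(G, G, D))
  fc <- sample_keypoint_features(Ipc, cbind(11.3, 17.8, 2), p, k = 3L)
  expect_equal(as.numeric(fc), as.numeric(1:D), tolerance = 1e-12)
  # k = 3 grid equals the mean of the 9 bilinear samples
  kp2 <- cbind(13.7, 9.2, 2)
  f3 <- sample_keypoint_features(Ip, kp2, p, k = 3L, stride = 1)
  cx <- 13.7 / p - 0.5; cy <- 9.2 / p - 0.5
  acc <- rep(0, D)
  for (oy in -1:1) for (ox in -1:1) acc <- acc + bilinear(cx + ox, cy + oy)
  expect_equal(as.numeric(f3), acc / 9, tolerance = 1e-12)
  # labeled keypoints must be finite
  expect_error(sample_keypoint_features(Ip, cbind(NA, 1, 2), p), "finite")
})

test_that("keypoint sampling is translation-consistent away from borders", {
  set.seed(10)
  G <- 10L; D <- 3L; p <- 4L
  base <- array(rnorm(G * G * D), dim = c(G, G, D))
  shifted <- base
  shifted[, 2:G, ] <- base[, 1:(G - 1), ]   # shift one cell right
  kp <- cbind(18.6, 22.1, 2)
  f1 <- sample_keypoint_features(base, kp, p, k = 3L)
  f2 <- sample_keypoint_features(shifted, kp + cbind(p, 0, 0), p, k = 3L)
  expect_equal(f1, f2, tolerance = 1e-10)
})
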