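# The autodiff tape must reproduce finite-difference gradients for every
# operation composition the model uses.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_grad_matches <- function(build, dims, tol = 1e-5) {
  x0 <- matrix(stats::rnorm(prod(dims)), dims[1L], dims[2L])
  p <- ag_param(x0)
  promptpose:::ag_backward(build(p))
  ng <- num_grad(function(xv) promptpose:::ag_value(build(ag_param(xv)))[1L], x0)
  expect_lt(max(abs(p$grad - ng)) / max(1e-8, max(abs(ng))), tol)
}

test_that("gradients of core ops match finite differences", {
  set.seed(42)
  W <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(3), 1)
  tgt <- matrix(rnorm(15), 5, 3)
  g1 <- matrix(rnorm(4), 1); b1 <- matrix(rnorm(4), 1)
  Qc <- matrix(rnorm(16), 4, 4)
  ag <- getNamespace("promptpose")
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_relu(ag$ag_affine(p, ag_const(W), ag_const(b))), tgt), c(5, 4))
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_layernorm_rows(p, ag_const(g1), ag_const(b1)),
                          matrix(0.3, 5, 4)), c(5, 4))
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_normalize_rows(p), matrix(0.1, 5, 4)), c(5, 4))
  expect_grad_matches(function(p) ag$ag_ce_diag(p), c(4, 4))
  expect_grad_matches(function(p)
    ag$ag_ce_diag(ag$ag_scalar_mul(ag_const(Qc), p)), c(1, 1))
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_softmax_rows(p), matrix(0.25, 4, 4)), c(4, 4))
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_cbind(ag$ag_gather_rows(p, c(1, 2, 2, 3)),
                                      ag$ag_gather_rows(p, c(3, 2, 1, 1))),
                          matrix(0, 4, 6)), c(3, 3))
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_exp(ag$ag_colmeans(p)), matrix(0.5, 1, 3)), c(5, 3))
})

test_that("gradients flow through a full transformer block", {
  set.seed(43)
  ag <- getNamespace("promptpose")
  blk <- ag$.init_block(6L)
  blkn <- ag$lapply_nodes(blk)
  tgt <- matrix(rnorm(30), 5, 6)
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_transformer_block(p, blkn), tgt), c(5, 6), tol = 1e-4)
  # and through a block parameter
  x0 <- matrix(rnorm(30), 5, 6)
  pW <- ag_param(blk$Wq)
  blkn2 <- ag$lapply_nodes(blk); blkn2$Wq <- pW
  loss <- ag$ag_masked_sse_mean(ag$ag_transformer_block(ag_const(x0), blkn2), tgt)
  promptpose:::ag_backward(loss)
  ng <- num_grad(function(wv) {
    blkn3 <- ag$lapply_nodes(blk); blkn3$Wq <- ag_const(wv)
    ag$ag_value(ag$ag_masked_sse_mean(ag$ag_transformer_block(ag_const(x0), blkn3), tgt))[1L]
  }, blk$Wq, eps = 1e-5)
  expect_lt(max(abs(pW$grad - ng)) / max(abs(ng)), 1e-4)
})

test_that("fused block-diagonal attention matches finite differences", {
  set.seed(44)
  ag <- getNamespace("promptpose")
  lens <- c(3L, 4L, 2L)
  K0 <- matrix(rnorm(9 * 4), 9, 4); V0 <- matrix(rnorm(9 * 4), 9, 4)
  tgt <- matrix(rnorm(36), 9, 4)
  # gradient w.r.t. queries
  expect_grad_matches(function(p)
    ag$ag_masked_sse_mean(ag$ag_sdp_attention(p, ag_const(K0), ag_const(V0),
                                              lens, 0.5), tgt), c(9, 4))
  # gradient w.r.t. keys and values
  Q0 <- matrix(rnorm(36), 9, 4)
  pK <- ag_param(K0); pV <- ag_param(V0)
  promptpose:::ag_backward(ag$ag_masked_sse_mean(
    ag$ag_sdp_attention(ag_const(Q0), pK, pV, lens, 0.5), tgt))
  ngK <- num_grad(function(kv) ag$ag_value(ag$ag_masked_sse_mean(
    ag$ag_sdp_attention(ag_const(Q0), ag_const(kv), ag_const(V0), lens, 0.5), tgt))[1L], K0)
  ngV <- num_grad(function(vv) ag$ag_value(ag$ag_masked_sse_mean(
    ag$ag_sdp_attention(ag_const(Q0), ag_const(K0), ag_const(vv), lens, 0.5), tgt))[1L], V0)
  expect_lt(max(abs(pK$grad - ngK)) / max(abs(ngK)), 1e-5)
  expect_lt(max(abs(pV$grad - ngV)) / max(abs(ngV)), 1e-5)
  # block structure: tokens of one sequence are unaffected by other sequences
  out1 <- ag$ag_value(ag$ag_sdp_attention(ag_const(Q0), ag_const(K0), ag_const(V0), lens, 0.5))
  K2 <- K0; K2[8:9, ] <- rnorm(8)   # perturb only the third block
  out2 <- ag$ag_value(ag$ag_sdp_attention(ag_const(Q0), ag_const(K2), ag_const(V0), lens, 0.5))
  expect_equal(out1[1:7, ], out2[1:7, ])
  expect_gt(max(abs(out1[8:9, ] - out2[8:9, ])), 0)
})

test_that("parameter gradients accumulate across backward passes and reset on demand", {
  p <- ag_param(matrix(c(1, 2), 1, 2))
  ag <- getNamespace("promptpose")
  build <- function() ag$ag_masked_sse_mean(p, matrix(0, 1, 2))
  promptpose:::ag_backward(build())
  g1 <- p$grad
  promptpose:::ag_backward(build())
  expect_equal(p$grad, 2 * g1)
  promptpose:::ag_zero_grads(list(p))
  expect_null(p$grad)
})

test_that("masked SSE restricts rows and honors the denominator override", {
  ag <- getNamespace("promptpose")
  pred <- matrix(1:6, 2, 3) * 1.0
  tgt <- pred * 0
  full <- ag$ag_value(ag$ag_masked_sse_mean(ag_const(pred), tgt))[1L]
  expect_equal(full, sum(pred^2) / 2)
  row1 <- ag$ag_value(ag$ag_masked_sse_mean(ag_const(pred), tgt, c(TRUE, FALSE)))[1L]
  expect_equal(row1, sum(pred[1, ]^2))
  denom <- ag$ag_value(ag$ag_masked_sse_mean(ag_const(pred), tgt, denom = 5))[1L]
  expect_equal(denom, sum(pred^2) / 5)
})
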