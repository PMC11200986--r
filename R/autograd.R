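# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every tensor in the computation graph is a node: an environment holding a
# numeric matrix `value`, its accumulated gradient `grad`, the parent nodes it
# was computed from, and a backward closure mapping the incoming gradient to
# one gradient per parent. Scalars are 1x1 matrices. The graph is rebuilt on
# every forward pass; parameter nodes persist across passes and collect
# gradients until reset. Sizes here are tiny (widths of a few dozen, token
# counts in the hundreds), so plain BLAS-backed matrix ops are sufficient.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

ag_new_id <- function() {
  .ag_env$counter <- .ag_env$counter + 1L
  .ag_env$counter
}

#' Create an autodiff graph node
#'
#' Low-level constructor used by all graph operations. Users normally create
#' leaves with [ag_const()] or [ag_param()] and build the rest with the
#' `ag_*` operations.
#'
#' @param value numeric matrix (scalars as 1x1 matrices).
#' @param parents list of parent `ag_node` objects.
#' @param backward function(grad) returning a list with one gradient matrix
#'   per parent, or `NULL` for leaves.
#' @return an object of class `ag_node`.
#' @keywords internal
ag_node <- function(value, parents = list(), backward = NULL) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  stopifnot(is.numeric(value))
  e <- new.env(parent = emptyenv())
  e$id <- ag_new_id()
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$requires <- length(parents) > 0L && any(vapply(parents, function(p) p$requires, logical(1)))
  class(e) <- "ag_node"
  e
}

#' @rdname ag_node
#' @param x numeric matrix or vector.
#' @export
ag_const <- function(x) {
  n <- ag_node(x)
  n$requires <- FALSE
  n
}

#' @rdname ag_node
#' @export
ag_param <- function(x) {
  n <- ag_node(x)
  n$requires <- TRUE
  n$is_param <- TRUE
  n
}

#' @export
print.ag_node <- function(x, ...) {
  cat(sprintf("<ag_node %d: %dx%d%s>\n", x$id, nrow(x$value), ncol(x$value),
              if (isTRUE(x$is_param)) " param" else ""))
  invisible(x)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x
as_node <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

# ---- elementary operations -------------------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply by a plain scalar constant
ag_scale <- function(a, s) {
  a <- as_node(a)
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

# multiply by a 1x1 scalar node (e.g. a learnable temperature)
ag_scalar_mul <- function(a, s) {
  a <- as_node(a); s <- as_node(s)
  av <- a$value; sv <- s$value[1L]
  ag_node(av * sv, list(a, s), function(g)
    list(g * sv, matrix(sum(g * av), 1L, 1L)))
}

ag_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), crossprod(av, g)))
}

ag_t <- function(a) {
  a <- as_node(a)
  ag_node(t(a$value), list(a), function(g) list(t(g)))
}

# add a length-k row vector to every row of an n x k matrix (cheaper than sweep)
.add_rv <- function(m, v) m + rep(v, each = nrow(m))

# x %*% W + bias broadcast over rows; fused for fewer graph nodes
ag_affine <- function(x, W, b) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  xv <- x$value; Wv <- W$value
  out <- .add_rv(xv %*% Wv, as.numeric(b$value))
  ag_node(out, list(x, W, b), function(g)
    list(g %*% t(Wv), crossprod(xv, g), matrix(colSums(g), 1L)))
}

# add a 1xk row-vector node to every row of an n x k node
ag_add_rowvec <- function(a, v) {
  a <- as_node(a); v <- as_node(v)
  out <- .add_rv(a$value, as.numeric(v$value))
  ag_node(out, list(a, v), function(g) list(g, matrix(colSums(g), 1L)))
}

ag_relu <- function(a) {
  a <- as_node(a)
  keep <- a$value > 0
  ag_node(a$value * keep, list(a), function(g) list(g * keep))
}

ag_exp <- function(a) {
  a <- as_node(a)
  ev <- exp(a$value)
  ag_node(ev, list(a), function(g) list(g * ev))
}

# column means as a 1xk row vector (global average pooling over grid cells)
ag_colmeans <- function(a) {
  a <- as_node(a)
  n <- nrow(a$value)
  ag_node(matrix(colMeans(a$value), 1L), list(a), function(g)
    matrix(rep(as.numeric(g) / n, each = n), nrow = n) |> list())
}

# row gather with scatter-add backward; idx may repeat
ag_gather_rows <- function(a, idx) {
  a <- as_node(a)
  n <- nrow(a$value)
  ag_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, idx)                 # C-level scatter-add over row groups
    out <- matrix(0, n, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ag_rbind <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  na <- nrow(a$value)
  ag_node(rbind(a$value, b$value), list(a, b), function(g)
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE]))
}

ag_cbind <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ka <- ncol(a$value)
  ag_node(cbind(a$value, b$value), list(a, b), function(g)
    list(g[, seq_len(ka), drop = FALSE], g[, -seq_len(ka), drop = FALSE]))
}

# row-wise softmax with optional additive mask (a constant matrix of 0 / -Inf)
ag_softmax_rows <- function(a, mask = NULL) {
  a <- as_node(a)
  z <- a$value
  if (!is.null(mask)) z <- z + mask
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  p <- exp(z)
  p <- p / rowSums(p)
  ag_node(p, list(a), function(g) {
    s <- rowSums(g * p)
    list(p * (g - s))
  })
}

# per-row layer normalization with learnable gain/bias (1xk nodes)
ag_layernorm_rows <- function(x, gain, bias, eps = 1e-5) {
  x <- as_node(x); gain <- as_node(gain); bias <- as_node(bias)
  xv <- x$value
  k <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(gain$value)
  out <- .add_rv(xhat * rep(gv, each = nrow(xv)), as.numeric(bias$value))
  ag_node(out, list(x, gain, bias), function(g) {
    gg <- sweep(g, 2L, gv, "*")           # dL/dxhat
    m1 <- rowMeans(gg)
    m2 <- rowMeans(gg * xhat)
    dx <- inv * (gg - m1 - xhat * m2)
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

# L2-normalize each row; rows must have nonzero norm
ag_normalize_rows <- function(a, eps = 0) {
  a <- as_node(a)
  xv <- a$value
  nr <- sqrt(rowSums(xv^2)) + eps
  if (any(nr == 0)) stop("cannot L2-normalize a zero-norm row")
  y <- xv / nr
  ag_node(y, list(a), function(g) {
    s <- rowSums(g * y)
    list((g - y * s) / nr)
  })
}

# mean squared error, restricted to rows with mask TRUE:
#   sum_r mask_r * |pred_r - target_r|^2 / denom
# denom defaults to the number of unmasked rows (per-keypoint averaging).
ag_masked_sse_mean <- function(pred, target, rowmask = NULL, denom = NULL) {
  pred <- as_node(pred)
  tv <- ag_value(target)
  pv <- pred$value
  if (!all(dim(pv) == dim(tv))) stop("shape mismatch in masked MSE")
  if (is.null(rowmask)) rowmask <- rep(TRUE, nrow(pv))
  n <- if (is.null(denom)) sum(rowmask) else denom
  if (n == 0L) return(ag_const(matrix(0, 1L, 1L)))
  d <- pv - tv
  d[!rowmask, ] <- 0
  val <- sum(d^2) / n
  ag_node(matrix(val, 1L, 1L), list(pred), function(g)
    list(2 * as.numeric(g) * d / n))
}

# cross-entropy of row-softmaxed logits against the identity assignment:
#   -mean_m log softmax(logits)[m, m]
ag_ce_diag <- function(logits) {
  logits <- as_node(logits)
  z <- logits$value
  if (nrow(z) != ncol(z)) stop("diagonal cross-entropy needs a square matrix")
  m <- nrow(z)
  z <- z - apply(z, 1L, max)
  p <- exp(z); p <- p / rowSums(p)
  val <- -mean(log(pmax(diag(p), .Machine$double.xmin)))
  ag_node(matrix(val, 1L, 1L), list(logits), function(g) {
    d <- p
    diag(d) <- diag(d) - 1
    list(as.numeric(g) * d / m)
  })
}

# fused scaled-dot-product attention: out = softmax(scale * Q K^T) V,
# evaluated independently per consecutive row block when `lengths` is given
# (block-diagonal attention; tokens attend only within their own sequence).
# Fusing avoids materializing the full N x N score matrix for masked inputs
# and keeps the backward pass allocation-light.
ag_sdp_attention <- function(Q, K, V, lengths = NULL, scale = 1) {
  Q <- as_node(Q); K <- as_node(K); V <- as_node(V)
  Qv <- Q$value; Kv <- K$value; Vv <- V$value
  n <- nrow(Qv)
  if (is.null(lengths)) lengths <- n
  stopifnot(sum(lengths) == n)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  A_list <- vector("list", length(lengths))
  out <- matrix(0, n, ncol(Vv))
  for (b in seq_along(lengths)) {
    i <- starts[b]:ends[b]
    z <- scale * tcrossprod(Qv[i, , drop = FALSE], Kv[i, , drop = FALSE])
    z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
    p <- exp(z)
    p <- p / rowSums(p)
    A_list[[b]] <- p
    out[i, ] <- p %*% Vv[i, , drop = FALSE]
  }
  ag_node(out, list(Q, K, V), function(g) {
    dQ <- matrix(0, n, ncol(Qv)); dK <- dQ; dV <- matrix(0, n, ncol(Vv))
    for (b in seq_along(lengths)) {
      i <- starts[b]:ends[b]
      A <- A_list[[b]]
      gi <- g[i, , drop = FALSE]
      dV[i, ] <- crossprod(A, gi)
      dA <- tcrossprod(gi, Vv[i, , drop = FALSE])
      dZ <- A * (dA - rowSums(dA * A))
      dQ[i, ] <- scale * dZ %*% Kv[i, , drop = FALSE]
      dK[i, ] <- scale * crossprod(dZ, Qv[i, , drop = FALSE])
    }
    list(dQ, dK, dV)
  })
}

# ---- backward pass ---------------------------------------------------------

#' Run backpropagation from a scalar node
#'
#' Topologically sorts the graph below `root`, seeds its gradient with 1 and
#' accumulates gradients into every reachable node (parameter nodes keep
#' theirs until [ag_zero_grads()] is called).
#'
#' @param root a 1x1 `ag_node` (typically a loss).
#' @return invisibly, the list of visited nodes.
#' @keywords internal
ag_backward <- function(root) {
  stopifnot(inherits(root, "ag_node"), length(root$value) == 1L)
  # iterative DFS topological order
  order <- vector("list", 256L); norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires || isTRUE(p$is_param)) {
          if (is.null(seen[[as.character(p$id)]]))
            stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  order <- order[seq_len(norder)]
  # reset intermediate gradients; parameter nodes keep accumulating so that
  # minibatch gradients can be summed across per-sample backward passes
  for (n in order) if (!isTRUE(n$is_param)) n$grad <- NULL
  root$grad <- matrix(1, 1L, 1L)
  # children come after parents in `order`; walk in reverse insertion order
  for (i in rev(seq_len(norder))) {
    node <- order[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!(p$requires || isTRUE(p$is_param))) next
      gj <- gs[[j]]
      if (is.null(gj)) next
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(order)
}

#' @rdname ag_backward
#' @param params list of parameter nodes.
#' @keywords internal
ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
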