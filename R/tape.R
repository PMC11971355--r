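# Minimal reverse-mode automatic differentiation on numeric arrays.
#
# A tape records nodes in creation order; because every op only consumes
# previously created nodes, creation order is a topological order and the
# backward sweep simply walks it in reverse. Values are matrices (batch x d)
# or 3-D arrays (batch x positions x d); 3-D arrays are reshaped to
# (batch*positions) x d for last-dimension linear algebra, which is exact in
# column-major layout because the first two dimensions vary fastest.
# Gradients are verified against central finite differences in the test suite.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, val, parents = NULL, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  if (!is.null(tape)) {
    if (tape$n == length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

tp_leaf <- function(tape, val) tp_node(tape, val)

tp_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar loss node.
tp_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents))
      if (!is.null(gs[[j]])) tp_accum(nd$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

.as2d <- function(v) {
  d <- dim(v)
  if (length(d) == 3L) matrix(v, d[1] * d[2], d[3]) else v
}
.restore <- function(m, template_dim) {
  if (length(template_dim) == 3L) array(m, template_dim) else m
}

# y = x W + b on the last dimension; x is 2-D or 3-D, W (d_in x d_out),
# b length d_out or NULL.
tp_linear <- function(tape, x, W, b = NULL) {
  xd <- dim(x$val)
  xm <- .as2d(x$val)
  out2 <- xm %*% W$val
  if (!is.null(b)) out2 <- sweep(out2, 2L, b$val, "+")
  odim <- if (length(xd) == 3L) c(xd[1], xd[2], ncol(W$val)) else dim(out2)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  tp_node(tape, .restore(out2, odim), parents, function(g) {
    g2 <- .as2d(g)
    gx <- .restore(g2 %*% t(W$val), xd)
    gW <- crossprod(xm, g2)
    if (is.null(b)) list(gx, gW) else list(gx, gW, colSums(g2))
  })
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

tp_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  tp_node(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

tp_scale_const <- function(tape, x, c) {
  tp_node(tape, x$val * c, list(x), function(g) list(g * c))
}

# Add a constant (k x d) positional-encoding matrix to every batch row of a
# (B x k x d) activation.
tp_add_const_pe <- function(tape, x, pe) {
  d <- dim(x$val)
  peb <- aperm(array(pe, c(dim(pe), d[1])), c(3, 1, 2))
  tp_node(tape, x$val + peb, list(x), function(g) list(g))
}

tp_sigmoid <- function(tape, x) {
  ov <- 1 / (1 + exp(-x$val))
  tp_node(tape, ov, list(x), function(g) list(g * ov * (1 - ov)))
}

tp_tanh <- function(tape, x) {
  ov <- tanh(x$val)
  tp_node(tape, ov, list(x), function(g) list(g * (1 - ov^2)))
}

tp_relu <- function(tape, x) {
  mask <- x$val > 0
  tp_node(tape, x$val * mask, list(x), function(g) list(g * mask))
}

tp_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  mask <- array(stats::rbinom(length(x$val), 1L, 1 - rate) / (1 - rate),
                dim(x$val))
  tp_node(tape, x$val * mask, list(x), function(g) list(g * mask))
}

# Column slice of a 2-D activation.
tp_slice_cols <- function(tape, x, idx) {
  xd <- dim(x$val)
  tp_node(tape, x$val[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, xd[1], xd[2])
    gx[, idx] <- g
    list(gx)
  })
}

# Last-dimension slice of a 3-D activation.
tp_slice_last3 <- function(tape, x, idx) {
  xd <- dim(x$val)
  tp_node(tape, x$val[, , idx, drop = FALSE], list(x), function(g) {
    gx <- array(0, xd)
    gx[, , idx] <- g
    list(gx)
  })
}

# Position t of a (B x k x d) activation as a (B x d) matrix.
tp_slice_pos <- function(tape, x, t) {
  xd <- dim(x$val)
  tp_node(tape, matrix(x$val[, t, ], xd[1], xd[3]), list(x), function(g) {
    gx <- array(0, xd)
    gx[, t, ] <- g
    list(gx)
  })
}

# Stack k (B x d) matrices into (B x k x d).
tp_stack_pos <- function(tape, xs) {
  B <- nrow(xs[[1]]$val); d <- ncol(xs[[1]]$val); k <- length(xs)
  out <- array(0, c(B, k, d))
  for (t in seq_len(k)) out[, t, ] <- xs[[t]]$val
  tp_node(tape, out, xs, function(g) {
    lapply(seq_len(k), function(t) matrix(g[, t, ], B, d))
  })
}

# Concatenate on the last dimension (2-D cbind or 3-D).
tp_concat_last <- function(tape, a, b) {
  ad <- dim(a$val); bd <- dim(b$val)
  if (length(ad) == 2L) {
    out <- cbind(a$val, b$val)
    tp_node(tape, out, list(a, b), function(g)
      list(g[, seq_len(ad[2]), drop = FALSE],
           g[, ad[2] + seq_len(bd[2]), drop = FALSE]))
  } else {
    out <- array(0, c(ad[1], ad[2], ad[3] + bd[3]))
    out[, , seq_len(ad[3])] <- a$val
    out[, , ad[3] + seq_len(bd[3])] <- b$val
    tp_node(tape, out, list(a, b), function(g)
      list(g[, , seq_len(ad[3]), drop = FALSE],
           g[, , ad[3] + seq_len(bd[3]), drop = FALSE]))
  }
}

# Row-wise dot product of two (B x d) matrices -> (B x 1).
tp_rowdot <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  tp_node(tape, matrix(rowSums(av * bv), nrow(av), 1L), list(a, b),
          function(g) {
            gv <- as.vector(g)
            list(bv * gv, av * gv)
          })
}

# Scale rows of a (B x d) matrix by a (B x 1) column -> (B x d).
tp_rowscale <- function(tape, v, s) {
  vv <- v$val; sv <- as.vector(s$val)
  tp_node(tape, vv * sv, list(v, s), function(g)
    list(g * sv, matrix(rowSums(g * vv), nrow(vv), 1L)))
}

tp_softmax_rows <- function(tape, x) {
  z <- x$val - apply(x$val, 1L, max)
  e <- exp(z)
  ov <- e / rowSums(e)
  tp_node(tape, ov, list(x), function(g) {
    list((g - rowSums(g * ov)) * ov)
  })
}

# Layer normalization over the last dimension with learned gain/shift.
tp_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xd <- dim(x$val)
  xm <- .as2d(x$val)
  d <- ncol(xm)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat * rep(gamma$val, each = nrow(xm)), 2L, beta$val, "+")
  tp_node(tape, .restore(out, xd), list(x, gamma, beta), function(g) {
    g2 <- .as2d(g)
    dxhat <- sweep(g2, 2L, gamma$val, "*")
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - t1 - xhat * t2) * inv
    list(.restore(dx, xd), colSums(g2 * xhat), colSums(g2))
  })
}

# Fused softmax + cross-entropy. `labels` are 1-based class indices.
# Returns a scalar-loss node; the predicted probabilities are cached in
# attr "probs" on the node's environment.
tp_softmax_xent <- function(tape, logits, labels) {
  lv <- logits$val
  z <- lv - apply(lv, 1L, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  B <- nrow(lv)
  py <- probs[cbind(seq_len(B), labels)]
  loss <- -mean(log(pmax(py, 1e-12)))
  onehot <- matrix(0, B, ncol(lv))
  onehot[cbind(seq_len(B), labels)] <- 1
  nd <- tp_node(tape, loss, list(logits), function(g)
    list((probs - onehot) * (g / B)))
  nd$probs <- probs
  nd
}

softmax_rows <- function(x) {
  z <- x - apply(x, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
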