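#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos * 10000^(-2i/d))` and
#' `PE(pos, 2i+1) = cos(pos * 10000^(-2i/d))`, where `pos` is the 0-based base
#' position within the k-mer, `i` indexes the hidden dimension and `d` is the
#' hidden vector dimension. Used by the transformer encoder variant, which is
#' otherwise position-blind.
#'
#' @param pos 0-based position within the k-mer.
#' @param index 0-based hidden-dimension index (even indices are the sine
#'   components, odd the cosine components).
#' @param d hidden vector dimension (default 128).
#' @return encoding value.
#' @export
positional_encoding <- function(pos, index, d = 128) {
  stopifnot(pos >= 0, index >= 0)
  if (any(index >= d)) stop_fmt("index must be < d")
  i <- index %/% 2
  angle <- pos * 10000^(-2 * i / d)
  ifelse(index %% 2 == 0, sin(angle), cos(angle))
}

#' Positional-encoding matrix for a k-mer
#'
#' @param k sequence length.
#' @param d hidden dimension.
#' @return `k x d` matrix; row `pos + 1` holds the encoding of position `pos`.
#' @export
positional_encoding_matrix <- function(k, d) {
  outer(0:(k - 1), 0:(d - 1), function(p, j) positional_encoding(p, j, d))
}

# ---- parameter initialisation -------------------------------------------

glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

lstm_layer_params <- function(d_in, H) {
  list(W = glorot(d_in, 4 * H), U = glorot(H, 4 * H), b = rep(0, 4 * H))
}

# One bidirectional LSTM layer over a (B x k x d_in) activation.
# Returns list(out = (B x k x 2H) node, h_fwd_last, h_bwd_last) where the
# final states are the hidden vectors at each scan's end.
bilstm_layer <- function(tape, x, prm, H) {
  xd <- dim(x$val)
  B <- xd[1]; k <- xd[2]
  run_dir <- function(W, U, b, order) {
    h <- tp_leaf(tape, matrix(0, B, H))
    cc <- tp_leaf(tape, matrix(0, B, H))
    outs <- vector("list", k)
    for (t in order) {
      xt <- tp_slice_pos(tape, x, t)
      z <- tp_add(tape, tp_linear(tape, xt, W),
                  tp_linear(tape, h, U, b))
      ig <- tp_sigmoid(tape, tp_slice_cols(tape, z, 1:H))
      fg <- tp_sigmoid(tape, tp_slice_cols(tape, z, (H + 1):(2 * H)))
      gg <- tp_tanh(tape, tp_slice_cols(tape, z, (2 * H + 1):(3 * H)))
      og <- tp_sigmoid(tape, tp_slice_cols(tape, z, (3 * H + 1):(4 * H)))
      cc <- tp_add(tape, tp_mul(tape, fg, cc), tp_mul(tape, ig, gg))
      h <- tp_mul(tape, og, tp_tanh(tape, cc))
      outs[[t]] <- h
    }
    list(outs = outs, last = h)
  }
  fwd <- run_dir(prm$fwd$W, prm$fwd$U, prm$fwd$b, seq_len(k))
  bwd <- run_dir(prm$bwd$W, prm$bwd$U, prm$bwd$b, rev(seq_len(k)))
  per_pos <- lapply(seq_len(k), function(t)
    tp_concat_last(tape, fwd$outs[[t]], bwd$outs[[t]]))
  list(out = tp_stack_pos(tape, per_pos),
       h_fwd_last = fwd$last, h_bwd_last = bwd$last)
}

# Stacked bidirectional LSTM encoder; dropout between layers.
# dim is the per-position output width (2H).
bilstm_encoder <- function(tape, x, prms, dim, dropout, training) {
  H <- dim %/% 2L
  last <- NULL
  for (l in seq_along(prms)) {
    if (l > 1) x <- tp_dropout(tape, x, dropout, training)
    res <- bilstm_layer(tape, x, prms[[l]], H)
    x <- res$out
    last <- res
  }
  list(out = x,
       final = tp_concat_last(tape, last$h_fwd_last, last$h_bwd_last))
}

# ---- transformer --------------------------------------------------------

mha_params <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d))
}

transformer_layer_params <- function(d, ff) {
  list(attn = mha_params(d),
       ln1_g = rep(1, d), ln1_b = rep(0, d),
       ff_W1 = glorot(d, ff), ff_b1 = rep(0, ff),
       ff_W2 = glorot(ff, d), ff_b2 = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d))
}

# Multi-head self-attention over a (B x k x d) activation. Head h uses the
# contiguous column block of width d/heads of the joint q/k/v projections.
multihead_attention <- function(tape, x, prm, heads) {
  xd <- dim(x$val)
  k <- xd[2]; d <- xd[3]
  dh <- d %/% heads
  q <- tp_linear(tape, x, prm$Wq)
  kk <- tp_linear(tape, x, prm$Wk)
  v <- tp_linear(tape, x, prm$Wv)
  head_outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    qh <- tp_slice_last3(tape, q, cols)
    kh <- tp_slice_last3(tape, kk, cols)
    vh <- tp_slice_last3(tape, v, cols)
    kpos <- lapply(seq_len(k), function(t) tp_slice_pos(tape, kh, t))
    vpos <- lapply(seq_len(k), function(t) tp_slice_pos(tape, vh, t))
    out_pos <- vector("list", k)
    for (i in seq_len(k)) {
      qi <- tp_slice_pos(tape, qh, i)
      scores <- lapply(kpos, function(kj) tp_rowdot(tape, qi, kj))
      smat <- Reduce(function(a, b) tp_concat_last(tape, a, b), scores)
      alpha <- tp_softmax_rows(tape, tp_scale_const(tape, smat, 1 / sqrt(dh)))
      acc <- NULL
      for (j in seq_len(k)) {
        term <- tp_rowscale(tape, vpos[[j]],
                            tp_slice_cols(tape, alpha, j))
        acc <- if (is.null(acc)) term else tp_add(tape, acc, term)
      }
      out_pos[[i]] <- acc
    }
    head_outs[[h]] <- tp_stack_pos(tape, out_pos)
  }
  joined <- Reduce(function(a, b) tp_concat_last(tape, a, b), head_outs)
  tp_linear(tape, joined, prm$Wo)
}

# BERT-style block: residual + layer norm around attention and feedforward.
transformer_layer <- function(tape, x, prm, heads, dropout, training) {
  a <- multihead_attention(tape, x, prm$attn, heads)
  a <- tp_dropout(tape, a, dropout, training)
  x <- tp_layernorm(tape, tp_add(tape, x, a), prm$ln1_g, prm$ln1_b)
  f <- tp_linear(tape, tp_relu(tape, tp_linear(tape, x, prm$ff_W1, prm$ff_b1)),
                 prm$ff_W2, prm$ff_b2)
  f <- tp_dropout(tape, f, dropout, training)
  tp_layernorm(tape, tp_add(tape, x, f), prm$ln2_g, prm$ln2_b)
}

transformer_encoder <- function(tape, x, prms, heads, dropout, training) {
  for (l in seq_along(prms))
    x <- transformer_layer(tape, x, prms[[l]], heads, dropout, training)
  x
}
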