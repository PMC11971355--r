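#' Classifier architecture configuration
#'
#' The triple-encoder architecture: a sequence-feature encoder and a
#' signal-feature encoder run independently, their per-position outputs are
#' concatenated (so `combine_dim = seq_dim + sig_dim` must hold) and encoded
#' collaboratively by a third encoder, and a feedforward head emits two-class
#' probabilities. Both a bidirectional-LSTM and a transformer variant of the
#' encoders are available behind the same contract; each encoder can be
#' disabled (identity pass-through) for ablation.
#'
#' @param encoder `"bilstm"` or `"transformer"`.
#' @param k odd k-mer length (default 13).
#' @param seq_layers,sig_layers,combine_layers encoder depths (defaults 2/2/3).
#' @param seq_dim,sig_dim,combine_dim per-position feature dimensions
#'   (defaults 128/128/256); `combine_dim` must equal `seq_dim + sig_dim`.
#' @param dropout dropout rate between stacked layers (default 0.2).
#' @param num_classes number of output classes (2).
#' @param embed_dim learned base-embedding width (default 16).
#' @param heads attention heads for the transformer variant.
#' @param ff_mult transformer feedforward width as a multiple of the encoder
#'   dimension.
#' @param clf_dim hidden width of the feedforward classifier head.
#' @param use_seq_encoder,use_sig_encoder,use_combine_encoder ablation
#'   switches; a disabled encoder passes its (projected) input through.
#' @return object of class `meth_model_config`.
#' @export
meth_model_config <- function(encoder = c("bilstm", "transformer"), k = 13,
                              seq_layers = 2, sig_layers = 2,
                              combine_layers = 3, seq_dim = 128,
                              sig_dim = 128, combine_dim = seq_dim + sig_dim,
                              dropout = 0.2, num_classes = 2, embed_dim = 16,
                              heads = 4, ff_mult = 2, clf_dim = 128,
                              use_seq_encoder = TRUE, use_sig_encoder = TRUE,
                              use_combine_encoder = TRUE) {
  encoder <- match.arg(encoder)
  if (k %% 2 == 0 || k < 3) stop_fmt("k must be an odd integer >= 3")
  if (combine_dim != seq_dim + sig_dim)
    stop_fmt("combine_dim (%d) must equal seq_dim + sig_dim (%d): the combine
 encoder consumes the per-position concatenation of the two branches",
             combine_dim, seq_dim + sig_dim)
  if (dropout < 0 || dropout >= 1) stop_fmt("dropout must be in [0, 1)")
  if (encoder == "bilstm" &&
      (seq_dim %% 2 || sig_dim %% 2 || combine_dim %% 2))
    stop_fmt("bilstm encoder dimensions must be even (two directions)")
  if (encoder == "transformer" &&
      (seq_dim %% heads || sig_dim %% heads || combine_dim %% heads))
    stop_fmt("transformer encoder dimensions must be divisible by heads")
  structure(list(encoder = encoder, k = as.integer(k),
                 seq_layers = seq_layers, sig_layers = sig_layers,
                 combine_layers = combine_layers, seq_dim = seq_dim,
                 sig_dim = sig_dim, combine_dim = combine_dim,
                 dropout = dropout, num_classes = num_classes,
                 embed_dim = embed_dim, heads = heads, ff_mult = ff_mult,
                 clf_dim = clf_dim, use_seq_encoder = use_seq_encoder,
                 use_sig_encoder = use_sig_encoder,
                 use_combine_encoder = use_combine_encoder),
            class = "meth_model_config")
}

.encoder_params <- function(config, dim, layers, enabled) {
  if (!enabled || layers == 0) return(list())
  if (config$encoder == "bilstm") {
    H <- dim %/% 2L
    lapply(seq_len(layers), function(l) {
      d_in <- dim # first layer input is the projected branch, also width dim
      list(fwd = lstm_layer_params(d_in, H), bwd = lstm_layer_params(d_in, H))
    })
  } else {
    lapply(seq_len(layers), function(l)
      transformer_layer_params(dim, config$ff_mult * dim))
  }
}

#' Initialise model parameters
#'
#' @param config a [meth_model_config()].
#' @param seed integer seed for the Glorot-uniform draws.
#' @return nested list of numeric arrays.
#' @export
init_params <- function(config, seed = 1) {
  withr::with_seed(as.integer(seed), {
    list(
      embed_W = glorot(4, config$embed_dim),
      seq_proj_W = glorot(config$embed_dim + 4, config$seq_dim),
      seq_proj_b = rep(0, config$seq_dim),
      sig_proj_W = glorot(15, config$sig_dim),
      sig_proj_b = rep(0, config$sig_dim),
      seq_enc = .encoder_params(config, config$seq_dim, config$seq_layers,
                                config$use_seq_encoder),
      sig_enc = .encoder_params(config, config$sig_dim, config$sig_layers,
                                config$use_sig_encoder),
      comb_enc = .encoder_params(config, config$combine_dim,
                                 config$combine_layers,
                                 config$use_combine_encoder),
      clf_W1 = glorot(config$combine_dim, config$clf_dim),
      clf_b1 = rep(0, config$clf_dim),
      clf_W2 = glorot(config$clf_dim, config$num_classes),
      clf_b2 = rep(0, config$num_classes))
  })
}

#' Model parameter count
#'
#' A pure function of the architecture configuration: the transformer
#' variant's count does not change with k (positional encodings are fixed,
#' not learned).
#'
#' @param config a [meth_model_config()].
#' @return integer number of scalar parameters.
#' @export
param_count <- function(config) {
  sum(vapply(rapply(init_params(config, seed = 1), length, how = "unlist"),
             identity, numeric(1)))
}

# Wrap a nested parameter list into tape leaf nodes (same structure).
wrap_params <- function(tape, params) {
  rapply(params, function(v) tp_leaf(tape, v), classes = c("numeric", "matrix",
                                                           "array", "integer"),
         how = "replace")
}

# Extract accumulated gradients from a wrapped parameter structure,
# zeros where a parameter was unused.
collect_grads <- function(wrapped) {
  rapply(wrapped, function(nd) {
    if (is.null(nd$grad)) array(0, dim(as.array(nd$val))) else nd$grad
  }, classes = "environment", how = "replace")
}

# One-hot encode base codes (B x k matrix of 0..3) into (B x k x 4).
.onehot_bases <- function(codes) {
  B <- nrow(codes); k <- ncol(codes)
  out <- array(0, c(B, k, 4))
  for (b in 0:3) out[, , b + 1][codes == b] <- 1
  out
}

# Build the network on a tape. `batch` is list(seq = (B x k x 5),
# sig = (B x k x 15)); `pw` is the wrapped parameter structure.
# Returns the logits node.
.forward_graph <- function(tape, pw, config, batch, training, scaling = NULL) {
  dims <- dim(batch$seq)
  B <- dims[1]; k <- dims[2]
  if (k != config$k)
    stop_fmt("batch k-mer length %d does not match model k %d", k, config$k)
  codes <- matrix(batch$seq[, , 5], B, k)
  num <- batch$seq[, , 1:4, drop = FALSE]
  if (!is.null(scaling))
    for (j in 1:4)
      num[, , j] <- (num[, , j] - scaling$mean[j]) / scaling$sd[j]
  emb <- tp_linear(tape, tp_leaf(tape, .onehot_bases(codes)), pw$embed_W)
  xseq <- tp_linear(tape, tp_concat_last(tape, emb, tp_leaf(tape, num)),
                    pw$seq_proj_W, pw$seq_proj_b)
  xsig <- tp_linear(tape, tp_leaf(tape, batch$sig), pw$sig_proj_W,
                    pw$sig_proj_b)
  if (config$encoder == "transformer") {
    xseq <- tp_add_const_pe(tape, xseq,
                            positional_encoding_matrix(k, config$seq_dim))
    xsig <- tp_add_const_pe(tape, xsig,
                            positional_encoding_matrix(k, config$sig_dim))
  }
  run_enc <- function(x, prms, dim) {
    if (!length(prms)) return(list(out = x, final = NULL))
    if (config$encoder == "bilstm")
      bilstm_encoder(tape, x, prms, dim, config$dropout, training)
    else
      list(out = transformer_encoder(tape, x, prms, config$heads,
                                     config$dropout, training), final = NULL)
  }
  seq_out <- run_enc(xseq, pw$seq_enc, config$seq_dim)$out
  sig_out <- run_enc(xsig, pw$sig_enc, config$sig_dim)$out
  comb_in <- tp_concat_last(tape, seq_out, sig_out)
  comb <- run_enc(comb_in, pw$comb_enc, config$combine_dim)
  final <- if (config$encoder == "bilstm" && !is.null(comb$final)) {
    # hidden vectors at the sequence's end in both scan directions
    comb$final
  } else {
    # transformer (or ablated combine encoder): center-position hidden vector
    tp_slice_pos(tape, comb$out, (k + 1L) %/% 2L)
  }
  h <- tp_relu(tape, tp_linear(tape, final, pw$clf_W1, pw$clf_b1))
  h <- tp_dropout(tape, h, config$dropout, training)
  tp_linear(tape, h, pw$clf_W2, pw$clf_b2)
}

# Evaluation-mode forward over plain params; returns the (B x 2) probability
# matrix (columns: unmethylated, methylated).
.forward_probs <- function(params, config, batch, scaling = NULL) {
  tape <- tape_new()
  pw <- wrap_params(tape, params)
  logits <- .forward_graph(tape, pw, config, batch, training = FALSE,
                           scaling = scaling)
  softmax_rows(logits$val)
}

.features_batch <- function(features, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_features(features))
  list(seq = features$seq[idx, , , drop = FALSE],
       sig = features$sig[idx, , , drop = FALSE])
}

#' Forward pass: per-read methylation probabilities
#'
#' Runs the classifier in evaluation mode (dropout disabled; identical inputs
#' give identical outputs) and returns the two-class probabilities, which sum
#' to one by construction of the softmax head.
#'
#' @param model a fitted `meth_model` (or a list with `params`, `config` and
#'   optionally `scaling`).
#' @param features a `meth_features` object with matching k.
#' @param batch_size forward batch size.
#' @return data.frame: `read_id`, `chrom`, `pos`, `strand`, `p_meth`,
#'   `p_unmeth`.
#' @export
model_forward <- function(model, features, batch_size = 512L) {
  n <- n_features(features)
  p <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs <- .forward_probs(model$params, model$config,
                            .features_batch(features, idx), model$scaling)
    p[idx] <- probs[, 2]
  }
  data.frame(read_id = features$info$read_id, chrom = features$info$chrom,
             pos = features$info$pos, strand = features$info$strand,
             p_meth = p, p_unmeth = 1 - p, stringsAsFactors = FALSE)
}

#' Binary read classification by probability comparison
#'
#' A read is methylated when its methylation probability exceeds the
#' non-methylation probability, i.e. `p_meth > 0.5`; the tie `p_meth = 0.5`
#' is called unmethylated.
#'
#' @param p_meth numeric vector of methylation probabilities.
#' @return character vector over `"methylated"` / `"unmethylated"`.
#' @export
classify_read <- function(p_meth) {
  stopifnot(all(p_meth >= 0 & p_meth <= 1))
  ifelse(p_meth > 0.5, "methylated", "unmethylated")
}
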