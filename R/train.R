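#' K-mer-balanced sample selection
#'
#' The strict class-balancing rule: only k-mers present in both the positive
#' and the negative pool survive; for each surviving k-mer exactly
#' `min(n_pos(kmer), n_neg(kmer), k_max)` samples are drawn uniformly without
#' replacement from each side. The output is therefore balanced 1:1 overall
#' and per k-mer. Deterministic under `seed`; an empty k-mer intersection
#' yields empty outputs.
#'
#' @param pos_kmers character vector: the k-mer of each positive sample.
#' @param neg_kmers character vector: the k-mer of each negative sample.
#' @param k_max maximum samples retained per k-mer per side.
#' @param seed integer seed.
#' @return list with integer index vectors `pos` and `neg` into the inputs.
#' @export
balance_kmers <- function(pos_kmers, neg_kmers, k_max = 10000L, seed = 1) {
  stopifnot(k_max >= 1)
  k_comm <- sort(intersect(unique(pos_kmers), unique(neg_kmers)))
  withr::with_seed(as.integer(seed), {
    pos_idx <- integer(0)
    neg_idx <- integer(0)
    for (km in k_comm) {
      ip <- which(pos_kmers == km)
      ineg <- which(neg_kmers == km)
      k_count <- min(length(ip), length(ineg), k_max)
      pos_idx <- c(pos_idx, resample(ip, k_count))
      neg_idx <- c(neg_idx, resample(ineg, k_count))
    }
    list(pos = sort(pos_idx), neg = sort(neg_idx))
  })
}

#' Balance a labeled feature set by k-mer
#'
#' @param features a labeled `meth_features` object.
#' @param k_max maximum samples per k-mer per side.
#' @param seed integer seed.
#' @return a balanced labeled `meth_features` object.
#' @export
balance_features <- function(features, k_max = 10000L, seed = 1) {
  lab <- features$info$label
  if (anyNA(lab)) stop_fmt("all records must be labeled before balancing")
  ipos <- which(lab == 1L)
  ineg <- which(lab == 0L)
  sel <- balance_kmers(features$info$kmer[ipos], features$info$kmer[ineg],
                       k_max, seed)
  features_subset(features, sort(c(ipos[sel$pos], ineg[sel$neg])))
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive and stratified by label; deterministic under `seed`.
#'
#' @param labels integer label vector (0/1).
#' @param test_fraction fraction held out, strictly in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, test_fraction, seed = 1) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop_fmt("test_fraction must be strictly between 0 and 1")
  if (!length(labels)) stop_fmt("no records to split")
  withr::with_seed(as.integer(seed), {
    test <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_test <- round(test_fraction * length(idx))
      test <- c(test, resample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Training configuration
#'
#' Adam with first/second-moment decay rates 0.9 and 0.999; the initial
#' learning rate defaults to 0.001 for the bilstm variant and 0.0005 for the
#' transformer variant, and is decreased by 80% with each epoch
#' (`lr(e) = lr_initial * 0.2^e`). Cross-entropy loss, global gradient-norm
#' clipping, dropout between layers and early stopping on validation accuracy.
#'
#' @param batch_size minibatch size (default 256).
#' @param epochs maximum epochs (default 20).
#' @param lr_initial initial learning rate; `NULL` selects the per-encoder
#'   default.
#' @param lr_decay per-epoch learning-rate multiplier (default 0.2, i.e. an
#'   80% decrease per epoch).
#' @param beta1,beta2 Adam moment decay rates.
#' @param adam_eps Adam epsilon.
#' @param grad_clip global gradient-norm clip (default 1.0).
#' @param patience early-stopping patience in epochs beyond the best
#'   validation accuracy.
#' @param test_fraction fraction of samples held out internally as the test
#'   set used to select the best-performing model (default 0.01).
#' @param seed integer seed covering init, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return object of class `meth_train_control`.
#' @export
meth_train_control <- function(batch_size = 256L, epochs = 20L,
                               lr_initial = NULL, lr_decay = 0.2,
                               beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                               grad_clip = 1.0, patience = 3L,
                               test_fraction = 0.01, seed = 1L,
                               verbose = FALSE) {
  stopifnot(batch_size >= 1, epochs >= 1, lr_decay > 0,
            test_fraction > 0, test_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_initial = lr_initial,
                 lr_decay = lr_decay, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, grad_clip = grad_clip,
                 patience = as.integer(patience),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "meth_train_control")
}

# Flatten a nested numeric structure to one vector (for norms / copies).
.flat <- function(x) unlist(x, use.names = FALSE)

# Elementwise binary op over two identically shaped nested lists.
.map2 <- function(a, b, f) {
  if (is.list(a)) return(mapply(.map2, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  f(a, b)
}
.map1 <- function(a, f) {
  if (is.list(a)) return(lapply(a, .map1, f = f))
  f(a)
}

#' Fit the methylation classifier
#'
#' The single model-fitting entry point. Expects a labeled (and normally
#' k-mer-balanced) feature set; holds out `test_fraction` of the samples,
#' stratified by label, to monitor accuracy and keep the best-performing
#' parameters; trains with Adam under the per-epoch learning-rate decay,
#' cross-entropy loss and global gradient clipping; stops early when the
#' held-out accuracy has not improved for `patience` epochs.
#'
#' @param features labeled `meth_features`.
#' @param config a [meth_model_config()]; its `k` must match the features.
#' @param control a [meth_train_control()].
#' @param validation optional labeled `meth_features` used instead of the
#'   internal split.
#' @return object of class `meth_model` with elements `params` (best-epoch
#'   weights), `config`, `control`, `scaling`, `history` (per-epoch
#'   data.frame), `best_epoch`, `n_train`, `n_validation`.
#' @export
meth_train <- function(features, config = meth_model_config(),
                       control = meth_train_control(), validation = NULL) {
  lab <- features$info$label
  if (!n_features(features)) stop_fmt("empty training set")
  if (anyNA(lab)) stop_fmt("all records must be labeled")
  if (length(unique(lab)) < 2) stop_fmt("training set has a single class")
  if (features$k != config$k)
    stop_fmt("feature k (%d) does not match model k (%d)", features$k,
             config$k)
  lr0 <- if (!is.null(control$lr_initial)) control$lr_initial
  else if (config$encoder == "bilstm") 0.001 else 0.0005

  if (is.null(validation)) {
    sp <- split_train_test(lab, control$test_fraction, control$seed)
    train <- features_subset(features, sp$train)
    val <- features_subset(features, sp$test)
  } else {
    train <- features
    val <- validation
  }
  n <- n_features(train)
  # feature scaling for the four numeric sequence-feature columns, fit on
  # the training samples only
  scaling <- list(
    mean = vapply(1:4, function(j) mean(train$seq[, , j]), numeric(1)),
    sd = vapply(1:4, function(j) {
      s <- stats::sd(train$seq[, , j]); if (s > 0) s else 1
    }, numeric(1)))

  params <- init_params(config, control$seed)
  m1 <- .map1(params, function(v) v * 0)
  m2 <- m1
  step <- 0L
  y_train <- train$info$label + 1L
  y_val <- val$info$label + 1L
  eval_acc <- function(p, feats, y) {
    if (!n_features(feats)) return(NA_real_)
    probs <- numeric(0)
    for (s in seq(1L, n_features(feats), by = 512L)) {
      idx <- s:min(s + 511L, n_features(feats))
      probs <- c(probs, .forward_probs(p, config,
                                       .features_batch(feats, idx),
                                       scaling)[, 2])
    }
    mean((probs > 0.5) + 1L == y)
  }

  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), train_acc = numeric(0),
                        val_acc = numeric(0))
  best <- list(acc = -Inf, params = params, epoch = 0L)
  withr::with_seed(control$seed + 17L, {
    for (epoch in seq_len(control$epochs)) {
      lr <- lr0 * control$lr_decay^(epoch - 1L)
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (s in seq(1L, n, by = control$batch_size)) {
        idx <- ord[s:min(s + control$batch_size - 1L, n)]
        tape <- tape_new()
        pw <- wrap_params(tape, params)
        logits <- .forward_graph(tape, pw, config,
                                 .features_batch(train, idx),
                                 training = TRUE, scaling = scaling)
        loss <- tp_softmax_xent(tape, logits, y_train[idx])
        tp_backward(tape, loss)
        grads <- collect_grads(pw)
        gn <- sqrt(sum(.flat(grads)^2))
        if (is.finite(gn) && gn > control$grad_clip)
          grads <- .map1(grads, function(g) g * (control$grad_clip / gn))
        step <- step + 1L
        m1 <- .map2(m1, grads, function(m, g) control$beta1 * m +
                      (1 - control$beta1) * g)
        m2 <- .map2(m2, grads, function(m, g) control$beta2 * m +
                      (1 - control$beta2) * g^2)
        bc1 <- 1 - control$beta1^step
        bc2 <- 1 - control$beta2^step
        upd <- .map2(m1, m2, function(a, b)
          lr * (a / bc1) / (sqrt(b / bc2) + control$adam_eps))
        params <- .map2(params, upd, `-`)
        ep_loss <- ep_loss + loss$val * length(idx)
        ep_correct <- ep_correct +
          sum((loss$probs[, 2] > 0.5) + 1L == y_train[idx])
      }
      # tiny pools can round the internal split down to zero records; the
      # training accuracy then stands in for model selection
      vacc <- if (n_features(val) > 0) eval_acc(params, val, y_val)
      else ep_correct / n
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / n,
        train_acc = ep_correct / n, val_acc = vacc))
      if (control$verbose)
        message(sprintf("epoch %d  lr %.2e  loss %.4f  acc %.4f  val %.4f",
                        epoch, lr, ep_loss / n, ep_correct / n, vacc))
      if (!is.na(vacc) && vacc > best$acc)
        best <- list(acc = vacc, params = params, epoch = epoch)
      if (epoch - best$epoch > control$patience) break
    }
  })
  structure(list(params = best$params, config = config, control = control,
                 scaling = scaling, history = history,
                 best_epoch = best$epoch, n_train = n,
                 n_validation = n_features(val)),
            class = "meth_model")
}

#' @export
print.meth_model <- function(x, ...) {
  cat(sprintf(
    "meth_model (%s encoder, k = %d): %d parameters\n",
    x$config$encoder, x$config$k, param_count(x$config)))
  cat(sprintf("trained on %d samples (%d held out), best epoch %d, val acc %.4f\n",
              x$n_train, x$n_validation, x$best_epoch,
              max(x$history$val_acc, na.rm = TRUE)))
  invisible(x)
}

#' @method summary meth_model
#' @export
summary.meth_model <- function(object, ...) {
  print(object)
  cat("\nper-epoch history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @method coef meth_model
#' @export
coef.meth_model <- function(object, ...) {
  stats::setNames(.flat(object$params),
                  rep(names(rapply(object$params, length, how = "unlist")),
                      rapply(object$params, length, how = "unlist")))
}

#' @method plot meth_model
#' @export
plot.meth_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "b",
                    pch = c(1, 19), lty = 1,
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"),
                   pch = c(1, 19), lty = 1, col = 1:2)
  invisible(x)
}

#' Predict methylation probabilities for feature records
#'
#' @param object a fitted `meth_model`.
#' @param newdata a `meth_features` object.
#' @param type `"calls"` (data.frame with per-read probabilities),
#'   `"prob"` (numeric `p_meth` vector) or `"class"` (binary call by the
#'   probability-comparison rule).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.meth_model <- function(object, newdata,
                               type = c("calls", "prob", "class"), ...) {
  type <- match.arg(type)
  calls <- model_forward(object, newdata)
  switch(type,
         calls = calls,
         prob = calls$p_meth,
         class = classify_read(calls$p_meth))
}
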