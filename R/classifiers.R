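#' Specify a classifier on embedding-space inputs
#'
#' Three modest architectures for the train-synthetic-test-real and
#' augmentation experiments: a fully connected network on the flattened
#' live coefficients (`"mlp"`), a small 1D convolutional stack over the
#' gene axis with global average pooling (`"cnn"`), and a compact
#' transformer encoder over gene patches (`"transformer"`). All train with
#' Adam on cross-entropy, with early stopping on a stratified validation
#' split; the full configuration and seed are recorded in the fitted model.
#'
#' @param architecture `"mlp"`, `"cnn"` or `"transformer"`.
#' @param n_classes number of classes `K >= 2`.
#' @param hidden hidden widths of the MLP.
#' @param channels convolution channels of the CNN stack.
#' @param patch,d_model,n_heads transformer patch size, token width, heads.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @param val_fraction validation fraction for early stopping.
#' @param seed training seed.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(architecture = c("mlp", "cnn", "transformer"),
                            n_classes = 2, hidden = c(128, 64),
                            channels = c(16, 32), patch = 8, d_model = 32,
                            n_heads = 2, epochs = 40, batch_size = 32,
                            lr = 1e-3, patience = 6, val_fraction = 0.15,
                            seed = 1L) {
  architecture <- match.arg(architecture)
  gd_assert(n_classes >= 2, "need at least two classes")
  structure(list(architecture = architecture, n_classes = as.integer(n_classes),
                 hidden = hidden, channels = channels, patch = as.integer(patch),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "classifier_spec")
}

classifier_inputs <- function(X) {
  if (inherits(X, "gene_embedding")) {
    list(flat = as_point_matrix(X), tensor = X$tensor,
         G = dim(X$tensor)[2])
  } else {
    list(flat = as.matrix(X), tensor = NULL, G = NA_integer_)
  }
}

init_classifier_params <- function(spec, d_in, G) {
  K <- spec$n_classes
  if (spec$architecture == "mlp") {
    dims <- c(d_in, spec$hidden, K)
    p <- list()
    for (l in seq_len(length(dims) - 1)) {
      p[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
      p[[paste0("b", l)]] <- zeros_row(dims[l + 1])
    }
    p
  } else if (spec$architecture == "cnn") {
    ch <- c(8, spec$channels)
    p <- list()
    for (l in seq_along(spec$channels)) {
      p[[paste0("W", l)]] <- glorot(3 * ch[l], ch[l + 1])
      p[[paste0("b", l)]] <- zeros_row(ch[l + 1])
    }
    p$head_W <- glorot(ch[length(ch)], K)
    p$head_b <- zeros_row(K)
    p
  } else {
    gd_assert(G %% spec$patch == 0, "patch must divide the gene axis")
    m <- spec$d_model
    list(patch_W = glorot(spec$patch * 8, m), patch_b = zeros_row(m),
         pos = matrix(rnorm((G %/% spec$patch) * m, sd = 0.02),
                      G %/% spec$patch, m),
         Wq = glorot(m, m), Wk = glorot(m, m), Wv = glorot(m, m),
         Wo = glorot(m, m),
         ffn_W1 = glorot(m, 2 * m), ffn_b1 = zeros_row(2 * m),
         ffn_W2 = glorot(2 * m, m), ffn_b2 = zeros_row(m),
         head_W = glorot(m, K), head_b = zeros_row(K))
  }
}

classifier_logits <- function(tape, spec, nodes, inputs, idx) {
  if (spec$architecture == "mlp") {
    h <- ad_const(tape, inputs$flat[idx, , drop = FALSE])
    L <- length(spec$hidden) + 1
    for (l in seq_len(L)) {
      h <- nn_linear(tape, h, nodes[[paste0("W", l)]], nodes[[paste0("b", l)]])
      if (l < L) h <- ad_relu(tape, h)
    }
    h
  } else if (spec$architecture == "cnn") {
    gd_assert(!is.null(inputs$tensor),
              "cnn classifier needs gene_embedding input")
    B <- length(idx)
    G <- inputs$G
    x <- inputs$tensor[idx, , , drop = FALSE]
    h <- ad_const(tape, matrix(x, B * G, 8))
    G_cur <- G
    for (l in seq_along(spec$channels)) {
      h <- ad_silu(tape, nn_conv3(tape, h, nodes[[paste0("W", l)]],
                                  nodes[[paste0("b", l)]], B, G_cur))
      if (G_cur %% 2L == 0L) {
        h <- nn_avgpool2(tape, h, B, G_cur)
        G_cur <- G_cur %/% 2L
      }
    }
    pooled <- ad_group_mean(tape, h, rep_len(seq_len(B), B * G_cur), B)
    nn_linear(tape, pooled, nodes$head_W, nodes$head_b)
  } else {
    gd_assert(!is.null(inputs$tensor),
              "transformer classifier needs gene_embedding input")
    B <- length(idx)
    G <- inputs$G
    p <- spec$patch
    S <- G %/% p
    x <- inputs$tensor[idx, , , drop = FALSE]
    perm <- patch_permutation(B, G, p)
    col <- ad_reshape(tape, ad_const(tape, matrix(x, B * G, 8)), B * G * 8L, 1L)
    tok_in <- ad_reshape(tape, ad_gather_rows(tape, col, perm), B * S, p * 8L)
    tok <- nn_linear(tape, tok_in, nodes$patch_W, nodes$patch_b)
    tok <- ad_add(tape, tok,
                  ad_gather_rows(tape, nodes$pos, rep(seq_len(S), each = B)))
    feats <- vector("list", B)
    for (b in seq_len(B)) {
      tb <- ad_gather_rows(tape, tok, b + (seq_len(S) - 1L) * B)
      a <- nn_attention(tape, ad_normalize_rows(tape, tb),
                        nodes$Wq, nodes$Wk, nodes$Wv, nodes$Wo, spec$n_heads)
      tb <- ad_add(tape, tb, a)
      f <- ad_silu(tape, nn_linear(tape, ad_normalize_rows(tape, tb),
                                   nodes$ffn_W1, nodes$ffn_b1))
      tb <- ad_add(tape, tb, nn_linear(tape, f, nodes$ffn_W2, nodes$ffn_b2))
      feats[[b]] <- ad_group_mean(tape, tb, rep(1L, S), 1L)
    }
    nn_linear(tape, ad_rbind(tape, feats), nodes$head_W, nodes$head_b)
  }
}

#' Train a classifier
#'
#' @param spec a [classifier_spec()].
#' @param X training inputs: a [gene_embedding()] (required for the cnn and
#'   transformer architectures) or a plain matrix for the MLP.
#' @param y 0-based class labels.
#' @return a fitted `classifier` object.
#' @export
train_classifier <- function(spec, X, y) {
  inputs <- classifier_inputs(X)
  y <- as.integer(y)
  gd_assert(length(unique(y)) >= 2,
            "training set contains a single class; cannot fit a classifier")
  gd_assert(all(y >= 0 & y < spec$n_classes), "labels out of range")
  n <- nrow(inputs$flat)
  with_local_seed(spec$seed, {
    params <- init_classifier_params(spec, ncol(inputs$flat), inputs$G)
    # stratified validation split for early stopping
    val_idx <- unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, max(1, round(spec$val_fraction * length(ix))))))
    fit_idx <- setdiff(seq_len(n), val_idx)
    state <- adam_init(params)
    best <- list(acc = -Inf, params = params, epoch = 0L)
    stale <- 0L
    for (ep in seq_len(spec$epochs)) {
      sh <- sample(fit_idx)
      for (chunk in split(sh, ceiling(seq_along(sh) / spec$batch_size))) {
        tape <- ad_tape()
        nodes <- ad_param_nodes(tape, params)
        logits <- classifier_logits(tape, spec, nodes, inputs, chunk)
        loss <- ad_cross_entropy(tape, logits, y[chunk] + 1L)
        ad_backward(tape, loss)
        upd <- adam_step(params, ad_collect_grads(nodes, params), state,
                         lr = spec$lr)
        params <- upd$params
        state <- upd$state
      }
      model_ep <- structure(list(spec = spec, params = params), class = "classifier")
      acc <- classifier_accuracy(model_ep, subset_inputs(inputs, val_idx),
                                 y[val_idx])
      if (acc > best$acc + 1e-9) {
        best <- list(acc = acc, params = params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= spec$patience) break
      }
    }
    structure(list(spec = spec, params = best$params,
                   val_accuracy = best$acc, best_epoch = best$epoch),
              class = "classifier")
  })
}

subset_inputs <- function(inputs, idx) {
  list(flat = inputs$flat[idx, , drop = FALSE],
       tensor = if (is.null(inputs$tensor)) NULL
                else inputs$tensor[idx, , , drop = FALSE],
       G = inputs$G)
}

classifier_accuracy <- function(model, inputs, y) {
  mean(predict_inputs(model, inputs) == y)
}

predict_inputs <- function(model, inputs) {
  n <- nrow(inputs$flat)
  preds <- integer(n)
  # chunked inference keeps the tape small
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 256))) {
    tape <- ad_tape()
    nodes <- lapply(model$params, function(p) ad_const(tape, p))
    logits <- classifier_logits(tape, model$spec, nodes, inputs, chunk)
    preds[chunk] <- max.col(logits$value, ties.method = "first") - 1L
  }
  preds
}

#' Predict class labels with a fitted classifier
#' @param object a `classifier` from [train_classifier()].
#' @param newdata a [gene_embedding()] or matrix.
#' @param ... unused.
#' @return integer vector of 0-based predicted labels.
#' @export
predict.classifier <- function(object, newdata, ...) {
  predict_inputs(object, classifier_inputs(newdata))
}

#' @exportS3Method base::print
print.classifier <- function(x, ...) {
  cat(sprintf("classifier '%s' (K=%d), val accuracy %.3f at epoch %d\n",
              x$spec$architecture, x$spec$n_classes, x$val_accuracy,
              x$best_epoch))
  invisible(x)
}

#' Accuracy of a classifier on labelled data
#' @param model a fitted `classifier`.
#' @param X inputs.
#' @param y 0-based true labels.
#' @return accuracy in `[0,1]`.
#' @export
accuracy <- function(model, X, y) {
  mean(predict(model, X) == as.integer(y))
}
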