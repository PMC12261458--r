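#' Construct a noise-prediction network
#'
#' Four interchangeable architectures behind one interface: every denoiser
#' maps a batch of embeddings (`n x G_pad x 8`), normalised diffusion times
#' `t` in `[0,1]` and optional class labels `y` to a noise estimate of the
#' same shape.
#'
#' * `"unet_mlp"` — U-Net of fully connected blocks along the flattened
#'   gene axis: down blocks halve the representation, up blocks double it
#'   with additive skip connections from the matching down block;
#'   conditioning (sinusoidal `t` embedding plus a learned `y` embedding)
#'   is injected additively in the up blocks.
#' * `"unet_cnn"` — same topology but each level uses kernel-3 1D
#'   convolutions along the gene axis with the 8 embedding slots as input
#'   channels, average pooling for downsampling and nearest-neighbour
#'   upsampling.
#' * `"unet_mlp_cnn"` — the learned combination
#'   `(1 - lambda(t)) * MLP(x,t,y) + lambda(t) * CNN(x,t,y)`, where
#'   `lambda(t)` is a two-layer perceptron of the normalised time with a
#'   sigmoid output, trained jointly with both submodels.
#' * `"transformer"` — genes are grouped into patches, each patch linearly
#'   embedded to one token; learnable positional embeddings are added and
#'   two extra tokens carry `t` and `y`; a stack of self-attention encoder
#'   layers is followed by a linear projection back to patch space.
#'
#' @param arch architecture name.
#' @param G_pad padded gene-axis length (divisible by `2^depth` for the
#'   U-Nets, by `patch` for the transformer).
#' @param n_classes number of label classes `K` (conditioning vocabulary).
#' @param depth number of U-Net down/up levels.
#' @param base_channels channel width of the first convolutional level.
#' @param patch genes per transformer token.
#' @param d_model transformer token width.
#' @param n_heads,n_layers transformer attention heads and encoder layers.
#' @param seed optional seed for parameter initialisation.
#' @return an object of class `denoiser`.
#' @export
denoiser <- function(arch = c("unet_mlp", "unet_cnn", "unet_mlp_cnn",
                              "transformer"),
                     G_pad, n_classes, depth = 3, base_channels = 16,
                     patch = 8, d_model = 32, n_heads = 2, n_layers = 2,
                     seed = NULL) {
  arch <- match.arg(arch)
  cfg <- list(arch = arch, G_pad = as.integer(G_pad),
              n_classes = as.integer(n_classes), depth = as.integer(depth),
              base_channels = as.integer(base_channels),
              patch = as.integer(patch), d_model = as.integer(d_model),
              n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
              d_t = 16L, d_y = 16L)
  init <- function() {
    params <- switch(arch,
      unet_mlp = init_unet_mlp(cfg),
      unet_cnn = init_unet_cnn(cfg),
      unet_mlp_cnn = c(prefix_params(init_unet_mlp(cfg), "mlp."),
                       prefix_params(init_unet_cnn(cfg), "cnn."),
                       init_mixer(cfg)),
      transformer = init_transformer(cfg))
    params$y_embed <- matrix(rnorm(n_classes * cfg$d_y, sd = 0.1),
                             n_classes, cfg$d_y)
    params
  }
  params <- if (is.null(seed)) init() else with_local_seed(seed, init())
  structure(list(config = cfg, params = params, seed = seed),
            class = "denoiser")
}

prefix_params <- function(params, prefix) {
  names(params) <- paste0(prefix, names(params))
  params
}

subset_params <- function(nodes, prefix) {
  keep <- startsWith(names(nodes), prefix)
  out <- nodes[keep]
  names(out) <- substring(names(out), nchar(prefix) + 1)
  out
}

#' @exportS3Method base::print
print.denoiser <- function(x, ...) {
  cat(sprintf("denoiser '%s': G_pad=%d, K=%d, %d parameters\n",
              x$config$arch, x$config$G_pad, x$config$n_classes,
              denoiser_param_count(x)))
  invisible(x)
}

#' Number of trainable parameters of a denoiser
#' @param model a [denoiser()].
#' @return integer parameter count.
#' @export
denoiser_param_count <- function(model) {
  sum(vapply(model$params, length, 0L))
}

## ---- initialisers ----------------------------------------------------------

mlp_dims <- function(cfg) {
  G <- cfg$G_pad
  gd_assert(G %% 2^cfg$depth == 0,
            "gene axis ", G, " not divisible by 2^depth = ", 2^cfg$depth)
  as.integer(G * 8 / 2^(0:cfg$depth))
}

init_unet_mlp <- function(cfg) {
  D <- mlp_dims(cfg)
  d <- cfg$depth
  dc <- cfg$d_t + cfg$d_y
  p <- list()
  for (l in seq_len(d)) {
    p[[paste0("down_W", l)]] <- glorot(D[l], D[l + 1])
    p[[paste0("down_b", l)]] <- zeros_row(D[l + 1])
  }
  p$mid_W <- glorot(D[d + 1], D[d + 1])
  p$mid_b <- zeros_row(D[d + 1])
  for (l in seq_len(d)) {
    p[[paste0("up_W", l)]] <- glorot(D[l + 1], D[l])
    p[[paste0("up_b", l)]] <- zeros_row(D[l])
    p[[paste0("cond_W", l)]] <- glorot(dc, D[l]) * 0.1
  }
  p
}

cnn_channels <- function(cfg) {
  as.integer(c(8, cfg$base_channels * 2^(seq_len(cfg$depth) - 1)))
}

init_unet_cnn <- function(cfg) {
  gd_assert(cfg$G_pad %% 2^cfg$depth == 0,
            "gene axis ", cfg$G_pad, " not divisible by 2^depth = ", 2^cfg$depth)
  ch <- cnn_channels(cfg)
  d <- cfg$depth
  dc <- cfg$d_t + cfg$d_y
  p <- list()
  for (l in seq_len(d)) {
    p[[paste0("down_W", l)]] <- glorot(3 * ch[l], ch[l + 1])
    p[[paste0("down_b", l)]] <- zeros_row(ch[l + 1])
  }
  p$mid_W <- glorot(3 * ch[d + 1], ch[d + 1])
  p$mid_b <- zeros_row(ch[d + 1])
  for (l in seq_len(d)) {
    cin <- if (l == d) ch[d + 1] else ch[l + 2]
    p[[paste0("up_W", l)]] <- glorot(3 * cin, ch[l + 1])
    p[[paste0("up_b", l)]] <- zeros_row(ch[l + 1])
    p[[paste0("cond_W", l)]] <- glorot(dc, ch[l + 1]) * 0.1
  }
  p$out_W <- glorot(3 * ch[2], 8)
  p$out_b <- zeros_row(8)
  p
}

init_mixer <- function(cfg, hidden = 16L) {
  list(lam_W1 = glorot(1, hidden), lam_b1 = zeros_row(hidden),
       lam_W2 = glorot(hidden, 1), lam_b2 = zeros_row(1))
}

init_transformer <- function(cfg) {
  gd_assert(cfg$G_pad %% cfg$patch == 0,
            "patch size ", cfg$patch, " does not divide gene axis ", cfg$G_pad)
  S <- cfg$G_pad %/% cfg$patch
  m <- cfg$d_model
  p <- list(patch_W = glorot(cfg$patch * 8, m), patch_b = zeros_row(m),
            pos = matrix(rnorm(S * m, sd = 0.02), S, m),
            t_W = glorot(cfg$d_t, m), t_b = zeros_row(m),
            y_W = glorot(cfg$d_y, m), y_b = zeros_row(m),
            out_W = glorot(m, cfg$patch * 8), out_b = zeros_row(cfg$patch * 8))
  for (l in seq_len(cfg$n_layers)) {
    p[[paste0("Wq", l)]] <- glorot(m, m)
    p[[paste0("Wk", l)]] <- glorot(m, m)
    p[[paste0("Wv", l)]] <- glorot(m, m)
    p[[paste0("Wo", l)]] <- glorot(m, m)
    p[[paste0("ffn_W1", l)]] <- glorot(m, 2 * m)
    p[[paste0("ffn_b1", l)]] <- zeros_row(2 * m)
    p[[paste0("ffn_W2", l)]] <- glorot(2 * m, m)
    p[[paste0("ffn_b2", l)]] <- zeros_row(m)
  }
  p
}

## ---- forwards --------------------------------------------------------------

# x_node: B x (G*8) flat node; t: numeric length B in [0,1]; y: labels or NULL.
# Returns a node of the same flat shape.
denoiser_forward <- function(tape, model, nodes, x_node, t, y, B) {
  cfg <- model$config
  switch(cfg$arch,
    unet_mlp = forward_unet_mlp(tape, cfg, nodes, x_node, t, y),
    unet_cnn = forward_unet_cnn(tape, cfg, nodes, x_node, t, y, B),
    unet_mlp_cnn = forward_combined(tape, cfg, nodes, x_node, t, y, B),
    transformer = forward_transformer(tape, cfg, nodes, x_node, t, y, B))
}

forward_unet_mlp <- function(tape, cfg, nodes, x_node, t, y) {
  d <- cfg$depth
  cond <- nn_condition(tape, nodes, t, y, cfg$n_classes, cfg$d_t)
  skips <- vector("list", d)
  h <- x_node
  for (l in seq_len(d)) {
    skips[[l]] <- h
    h <- ad_silu(tape, nn_linear(tape, h, nodes[[paste0("down_W", l)]],
                                 nodes[[paste0("down_b", l)]]))
  }
  h <- ad_silu(tape, nn_linear(tape, h, nodes$mid_W, nodes$mid_b))
  for (l in rev(seq_len(d))) {
    u <- nn_linear(tape, h, nodes[[paste0("up_W", l)]],
                   nodes[[paste0("up_b", l)]])
    u <- ad_add(tape, u, ad_matmul(tape, cond, nodes[[paste0("cond_W", l)]]))
    u <- ad_add(tape, u, skips[[l]])
    h <- if (l > 1) ad_silu(tape, u) else u   # last up block stays linear
  }
  h
}

forward_unet_cnn <- function(tape, cfg, nodes, x_node, t, y, B) {
  d <- cfg$depth
  G <- cfg$G_pad
  cond <- nn_condition(tape, nodes, t, y, cfg$n_classes, cfg$d_t)
  h <- ad_reshape(tape, x_node, B * G, 8L)   # row form
  skips <- vector("list", d)
  G_cur <- G
  for (l in seq_len(d)) {
    h <- ad_silu(tape, nn_conv3(tape, h, nodes[[paste0("down_W", l)]],
                                nodes[[paste0("down_b", l)]], B, G_cur))
    skips[[l]] <- list(node = h, G = G_cur)
    h <- nn_avgpool2(tape, h, B, G_cur)
    G_cur <- G_cur %/% 2L
  }
  h <- ad_silu(tape, nn_conv3(tape, h, nodes$mid_W, nodes$mid_b, B, G_cur))
  for (l in rev(seq_len(d))) {
    h <- nn_upsample2(tape, h, B, G_cur)
    G_cur <- G_cur * 2L
    h <- nn_conv3(tape, h, nodes[[paste0("up_W", l)]],
                  nodes[[paste0("up_b", l)]], B, G_cur)
    cemb <- ad_matmul(tape, cond, nodes[[paste0("cond_W", l)]])
    h <- ad_add(tape, h, nn_broadcast_rows(tape, cemb, B, G_cur))
    h <- ad_add(tape, h, skips[[l]]$node)
    h <- ad_silu(tape, h)
  }
  out <- nn_conv3(tape, h, nodes$out_W, nodes$out_b, B, G)
  ad_reshape(tape, out, B, G * 8L)
}

# lambda(t): two-layer perceptron with sigmoid output, one scalar per time
mixer_lambda <- function(tape, nodes, t) {
  tn <- ad_const(tape, matrix(t, ncol = 1))
  h <- ad_tanh(tape, nn_linear(tape, tn, nodes$lam_W1, nodes$lam_b1))
  ad_sigmoid(tape, nn_linear(tape, h, nodes$lam_W2, nodes$lam_b2))
}

forward_combined <- function(tape, cfg, nodes, x_node, t, y, B) {
  mlp_nodes <- subset_params(nodes, "mlp.")
  cnn_nodes <- subset_params(nodes, "cnn.")
  mlp_nodes$y_embed <- nodes$y_embed
  cnn_nodes$y_embed <- nodes$y_embed
  eps_mlp <- forward_unet_mlp(tape, cfg, mlp_nodes, x_node, t, y)
  eps_cnn <- forward_unet_cnn(tape, cfg, cnn_nodes, x_node, t, y, B)
  lam <- mixer_lambda(tape, nodes, t)               # B x 1 in [0,1]
  one_minus <- ad_addc(tape, ad_scale(tape, lam, -1), 1)
  ad_add(tape, ad_mul_rows(tape, eps_mlp, one_minus),
         ad_mul_rows(tape, eps_cnn, lam))
}

# permutation: row-form (B*G) x 8 -> patch tokens (B*S) x (patch*8)
patch_permutation <- function(B, G, patch) {
  S <- G %/% patch
  # target offset o = r + (j-1)*B*S, r = b + (i-1)*B, j = q + (c-1)*patch
  # source offset  = b + (g-1)*B + (c-1)*B*G, g = (i-1)*patch + q
  o <- seq_len(B * S * patch * 8)
  r <- (o - 1L) %% (B * S) + 1L
  j <- (o - 1L) %/% (B * S) + 1L
  b <- (r - 1L) %% B + 1L
  i <- (r - 1L) %/% B + 1L
  q <- (j - 1L) %% patch + 1L
  c <- (j - 1L) %/% patch + 1L
  g <- (i - 1L) * patch + q
  b + (g - 1L) * B + (c - 1L) * B * G
}

forward_transformer <- function(tape, cfg, nodes, x_node, t, y, B) {
  G <- cfg$G_pad
  p <- cfg$patch
  S <- G %/% p
  m <- cfg$d_model
  perm <- patch_permutation(B, G, p)
  col <- ad_reshape(tape, x_node, B * G * 8L, 1L)
  tok_in <- ad_reshape(tape, ad_gather_rows(tape, col, perm), B * S, p * 8L)
  tok <- nn_linear(tape, tok_in, nodes$patch_W, nodes$patch_b)
  pos <- ad_gather_rows(tape, nodes$pos, rep(seq_len(S), each = B))
  tok <- ad_add(tape, tok, pos)
  temb <- ad_const(tape, sinusoidal_embedding(t, cfg$d_t))
  ttok <- nn_linear(tape, temb, nodes$t_W, nodes$t_b)
  if (is.null(y)) {
    yin <- ad_const(tape, matrix(0, B, cfg$d_y))
  } else {
    yin <- ad_gather_rows(tape, nodes$y_embed, y + 1L)
  }
  ytok <- nn_linear(tape, yin, nodes$y_W, nodes$y_b)
  out_rows <- vector("list", B)
  for (b in seq_len(B)) {
    idx_b <- b + (seq_len(S) - 1L) * B
    tb <- ad_rbind(tape, list(ad_gather_rows(tape, tok, idx_b),
                              ad_gather_rows(tape, ttok, b),
                              ad_gather_rows(tape, ytok, b)))
    for (l in seq_len(cfg$n_layers)) {
      a <- nn_attention(tape, ad_normalize_rows(tape, tb),
                        nodes[[paste0("Wq", l)]], nodes[[paste0("Wk", l)]],
                        nodes[[paste0("Wv", l)]], nodes[[paste0("Wo", l)]],
                        cfg$n_heads)
      tb <- ad_add(tape, tb, a)
      f <- ad_silu(tape, nn_linear(tape, ad_normalize_rows(tape, tb),
                                   nodes[[paste0("ffn_W1", l)]],
                                   nodes[[paste0("ffn_b1", l)]]))
      f <- nn_linear(tape, f, nodes[[paste0("ffn_W2", l)]],
                     nodes[[paste0("ffn_b2", l)]])
      tb <- ad_add(tape, tb, f)
    }
    out_rows[[b]] <- ad_gather_rows(tape, tb, seq_len(S))
  }
  # stacked sample-major (i + (b-1)*S); permute back to row form (b + (i-1)*B)
  stacked <- ad_rbind(tape, out_rows)
  r <- seq_len(B * S)
  bb <- (r - 1L) %% B + 1L
  ii <- (r - 1L) %/% B + 1L
  tok_out <- ad_gather_rows(tape, stacked, ii + (bb - 1L) * S)
  patch_out <- nn_linear(tape, tok_out, nodes$out_W, nodes$out_b)
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  col_out <- ad_gather_rows(tape,
                            ad_reshape(tape, patch_out, B * G * 8L, 1L), inv)
  ad_reshape(tape, col_out, B, G * 8L)
}

#' Evaluate a denoiser without training
#'
#' Builds a throwaway tape, runs the forward pass and returns the noise
#' prediction as an array shaped like the input.
#'
#' @param model a [denoiser()].
#' @param x embedding tensor `n x G_pad x 8` (or flat `n x (G_pad*8)`).
#' @param t normalised time(s) in `[0,1]`, length 1 or n.
#' @param y class labels (0-based) or NULL for unconditional.
#' @return array `n x G_pad x 8` of predicted noise.
#' @export
denoiser_predict <- function(model, x, t, y = NULL) {
  if (is.function(model)) return(model(x, t, y))   # oracle predictors in tests
  flat <- if (length(dim(x)) == 3) flatten_batch(x) else x
  B <- nrow(flat)
  t <- rep_len(t, B)
  if (!is.null(y)) y <- rep_len(y, B)
  tape <- ad_tape()
  nodes <- lapply(model$params, function(p) ad_const(tape, p))
  out <- denoiser_forward(tape, model, nodes, ad_const(tape, flat), t, y, B)
  gd_assert(all(is.finite(out$value)), "denoiser produced non-finite output")
  unflatten_batch(out$value, model$config$G_pad)
}

#' Evaluate the learned mixing weight lambda(t)
#'
#' Only defined for the `"unet_mlp_cnn"` architecture.
#'
#' @param model a [denoiser()] of the combined architecture.
#' @param t normalised time(s) in `[0,1]`.
#' @return numeric vector of `lambda(t)` values in `[0,1]`.
#' @export
mixing_lambda <- function(model, t) {
  gd_assert(model$config$arch == "unet_mlp_cnn",
            "lambda(t) exists only for the combined architecture")
  tape <- ad_tape()
  nodes <- lapply(model$params, function(p) ad_const(tape, p))
  lam <- mixer_lambda(tape, nodes, t)$value[, 1]
  gd_assert(all(lam >= 0 & lam <= 1), "lambda(t) left [0,1]")
  lam
}

#' Save / load a denoiser checkpoint
#'
#' Single-file archive with the architecture tag, configuration, parameters
#' and seed.
#'
#' @param model a [denoiser()].
#' @param path file path.
#' @param codec_fingerprint optional codec checksum stored alongside.
#' @return `path` (save) or the denoiser (load).
#' @export
save_denoiser <- function(model, path, codec_fingerprint = NULL) {
  model$codec_fingerprint <- codec_fingerprint
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  gd_assert(inherits(model, "denoiser"), "file does not hold a denoiser")
  model
}
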