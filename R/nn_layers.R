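# Shared neural building blocks on top of the autodiff tape.
#
# Batch layout conventions (column-major flattening of an n x G x 8 array):
#   flat form:  B x (G*C) matrix, column j holds (gene g, channel c) with
#               g = ((j-1) %% G) + 1, c = ((j-1) %/% G) + 1
#   row form:   (B*G) x C matrix, row r holds (sample b, gene g) with
#               b = ((r-1) %% B) + 1, g = ((r-1) %/% B) + 1
# The two are plain reshapes of each other, so conversion is free.

flatten_batch <- function(x) {
  d <- dim(x)
  matrix(x, d[1], d[2] * d[3])
}

unflatten_batch <- function(m, G, C = 8) {
  array(m, c(nrow(m), G, C))
}

nn_linear <- function(tape, x, W, b = NULL) {
  out <- ad_matmul(tape, x, W)
  if (!is.null(b)) out <- ad_add(tape, out, b)
  out
}

# sinusoidal embedding of normalised time t in [0,1]; returns length(t) x d
sinusoidal_embedding <- function(t, d = 16) {
  half <- d %/% 2
  freqs <- exp(log(1000) * (seq_len(half) - 1) / max(1, half - 1))
  ang <- outer(t, freqs)
  cbind(sin(ang), cos(ang))
}

# conditioning vector per sample: sinusoidal t embedding + learned y rows;
# y = NULL (unconditional) contributes zeros. Returns a node B x (d_t + d_y).
nn_condition <- function(tape, nodes, t, y, K, d_t = 16) {
  temb <- ad_const(tape, sinusoidal_embedding(t, d_t))
  if (is.null(y)) {
    d_y <- ncol(nodes$y_embed$value)
    yemb <- ad_const(tape, matrix(0, length(t), d_y))
  } else {
    gd_assert(all(y >= 0 & y < K), "class index out of range 0..K-1")
    yemb <- ad_gather_rows(tape, nodes$y_embed, y + 1L)
  }
  ad_cbind(tape, list(temb, yemb))
}

## ---- row-form spatial ops (1D along the gene axis) ------------------------

# gather indices for shifting the gene axis by `offset`, zero row at B*G+1
shift_index <- function(B, G, offset) {
  g <- rep(seq_len(G), each = B)
  b <- rep(seq_len(B), G)
  gs <- g + offset
  ifelse(gs >= 1 & gs <= G, b + (gs - 1L) * B, B * G + 1L)
}

# 1D convolution, kernel 3, zero padding; x is (B*G) x C_in in row form
nn_conv3 <- function(tape, x, W, b, B, G) {
  C_in <- ncol(x$value)
  padded <- ad_rbind(tape, list(x, ad_const(tape, matrix(0, 1, C_in))))
  cols <- ad_cbind(tape, list(
    ad_gather_rows(tape, padded, shift_index(B, G, -1L)),
    ad_gather_rows(tape, padded, shift_index(B, G, 0L)),
    ad_gather_rows(tape, padded, shift_index(B, G, 1L))))
  nn_linear(tape, cols, W, b)
}

# average-pool the gene axis by 2: (B*G) x C -> (B*G/2) x C
nn_avgpool2 <- function(tape, x, B, G) {
  H <- G %/% 2L
  h <- rep(seq_len(H), each = B)
  b <- rep(seq_len(B), H)
  i1 <- b + (2L * h - 2L) * B
  i2 <- b + (2L * h - 1L) * B
  ad_scale(tape,
           ad_add(tape, ad_gather_rows(tape, x, i1), ad_gather_rows(tape, x, i2)),
           0.5)
}

# nearest-neighbour upsample of the gene axis by 2: (B*H) x C -> (B*2H) x C
nn_upsample2 <- function(tape, x, B, H) {
  G <- 2L * H
  g <- rep(seq_len(G), each = B)
  b <- rep(seq_len(B), G)
  src <- b + (ceiling(g / 2) - 1L) * B
  ad_gather_rows(tape, x, src)
}

# broadcast a per-sample B x C node to row form (B*G) x C
nn_broadcast_rows <- function(tape, emb, B, G) {
  ad_gather_rows(tape, emb, rep_len(seq_len(B), B * G))
}

## ---- attention ------------------------------------------------------------

# single-sample multi-head self-attention over S tokens of width m.
# tok: S x m node; Wq/Wk/Wv/Wo: m x m params; n_heads divides m.
nn_attention <- function(tape, tok, Wq, Wk, Wv, Wo, n_heads) {
  m <- ncol(tok$value)
  hd <- m %/% n_heads
  q <- ad_matmul(tape, tok, Wq)
  k <- ad_matmul(tape, tok, Wk)
  v <- ad_matmul(tape, tok, Wv)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    js <- (h - 1L) * hd + seq_len(hd)
    qh <- ad_cols(tape, q, js)
    kh <- ad_cols(tape, k, js)
    vh <- ad_cols(tape, v, js)
    scores <- ad_scale(tape, ad_matmul(tape, qh, ad_t(tape, kh)), 1 / sqrt(hd))
    attn <- ad_softmax_rows(tape, scores)
    heads[[h]] <- ad_matmul(tape, attn, vh)
  }
  ad_matmul(tape, ad_cbind(tape, heads), Wo)
}
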