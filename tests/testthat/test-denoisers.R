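G <- 16L
mask <- local({
  set.seed(51)
  m <- matrix(0, G, 8)
  for (g in 1:(G - 2)) m[g, seq_len(sample(1:8, 1))] <- 1  # 2 padded genes
  m
})
x4 <- random_clamped(4, mask, seed = 52)

make_model <- function(arch, ...) {
  denoiser(arch, G_pad = G, n_classes = 3, depth = 2, base_channels = 4,
           patch = 4, d_model = 8, n_heads = 2, n_layers = 1, seed = 53, ...)
}

test_that("all architectures satisfy the shape, finiteness and conditioning contract", {
  for (arch in c("unet_mlp", "unet_cnn", "unet_mlp_cnn", "transformer")) {
    m <- make_model(arch)
    out <- denoiser_predict(m, x4, t = c(.1, .4, .6, .9), y = c(0, 1, 2, 0))
    expect_equal(dim(out), dim(x4), info = arch)
    expect_true(all(is.finite(out)), info = arch)
    # conditioning is live: changing y changes the output
    out2 <- denoiser_predict(m, x4, t = c(.1, .4, .6, .9), y = c(1, 2, 0, 1))
    expect_gt(max(abs(out - out2)), 1e-8)
    # time is live too
    out3 <- denoiser_predict(m, x4, t = c(.9, .1, .2, .5), y = c(0, 1, 2, 0))
    expect_gt(max(abs(out - out3)), 1e-8)
    # unconditional evaluation works
    expect_equal(dim(denoiser_predict(m, x4, t = 0.5)), dim(x4))
  }
  expect_error(denoiser("unet_mlp", G_pad = 10, n_classes = 2, depth = 3),
               "divisible")
  expect_error(denoiser("transformer", G_pad = 10, n_classes = 2, patch = 4),
               "divide")
})

test_that("every parameter of the U-Net MLP and the mixer receives gradient", {
  sched <- noise_schedule(20)
  for (arch in c("unet_mlp", "unet_mlp_cnn")) {
    m <- make_model(arch)
    set.seed(54)
    st <- training_step(m, random_clamped(6, mask, seed = 55),
                        labels = c(0, 1, 2, 0, 1, 2), sched, mask)
    expect_true(is.finite(st$loss))
    zero_grads <- names(Filter(function(g) all(g == 0), st$grads))
    expect_length(zero_grads, 0)
  }
})

test_that("the combined model is the exact convex combination of its submodels", {
  mc <- make_model("unet_mlp_cnn")
  # extract the two submodels with shared y embedding
  sub <- function(prefix) {
    pp <- mc$params[startsWith(names(mc$params), prefix)]
    names(pp) <- substring(names(pp), nchar(prefix) + 1)
    pp$y_embed <- mc$params$y_embed
    m <- make_model(if (prefix == "mlp.") "unet_mlp" else "unet_cnn")
    m$params <- pp
    m
  }
  t <- c(.2, .5, .7, .9); y <- c(0, 1, 2, 1)
  out_mlp <- denoiser_predict(sub("mlp."), x4, t, y)
  out_cnn <- denoiser_predict(sub("cnn."), x4, t, y)

  m0 <- pinned_lambda_model(mc, 0)
  expect_equal(denoiser_predict(m0, x4, t, y), out_mlp, tolerance = 1e-12)
  m1 <- pinned_lambda_model(mc, 1)
  expect_equal(denoiser_predict(m1, x4, t, y), out_cnn, tolerance = 1e-12)
  mh <- pinned_lambda_model(mc, 0.5)
  expect_equal(denoiser_predict(mh, x4, t, y), (out_mlp + out_cnn) / 2,
               tolerance = 1e-12)

  lam <- mixing_lambda(mc, seq(0, 1, by = 0.1))
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(mixing_lambda(m1, 0.5), 1)
})

test_that("the convolutional U-Net is shift-equivariant in the interior and local", {
  # wide gene axis so the receptive field (about +/-14 genes at depth 2)
  # stays clear of the boundaries
  Gw <- 64L
  m <- denoiser("unet_cnn", G_pad = Gw, n_classes = 3, depth = 2,
                base_channels = 4, seed = 58)
  full <- matrix(1, Gw, 8)
  set.seed(56)
  x <- apply_clamp(array(rnorm(Gw * 8), c(1, Gw, 8)), full)
  shift <- 4L  # a multiple of 2^depth, so the pooling grid stays aligned
  xs <- x
  xs[1, , ] <- 0
  xs[1, (shift + 1):Gw, ] <- x[1, 1:(Gw - shift), ]
  out <- denoiser_predict(m, x, 0.5, 0)
  outs <- denoiser_predict(m, xs, 0.5, 0)
  interior <- 24:44   # at least one receptive field from both boundaries
  expect_equal(outs[1, interior, ], out[1, interior - shift, ],
               tolerance = 1e-9)

  # locality: perturbing gene 1 leaves the far end untouched
  xp <- x
  xp[1, 1, ] <- xp[1, 1, ] + 5
  outp <- denoiser_predict(m, xp, 0.5, 0)
  expect_equal(outp[1, Gw, ], out[1, Gw, ], tolerance = 1e-10)
  expect_gt(max(abs(outp[1, 1:3, ] - out[1, 1:3, ])), 1e-6)
})

test_that("the transformer is equivariant under joint patch/position permutation", {
  m <- make_model("transformer")
  p <- m$config$patch
  S <- G %/% p
  set.seed(57)
  perm <- sample(S)
  m2 <- m
  m2$params$pos <- m$params$pos[perm, , drop = FALSE]
  full <- matrix(1, G, 8)
  x <- apply_clamp(array(rnorm(2 * G * 8), c(2, G, 8)), full)
  xp <- x
  for (i in seq_len(S)) {
    src <- (perm[i] - 1L) * p + seq_len(p)
    dst <- (i - 1L) * p + seq_len(p)
    xp[, dst, ] <- x[, src, ]
  }
  out <- denoiser_predict(m, x, c(.3, .8), c(0, 2))
  outp <- denoiser_predict(m2, xp, c(.3, .8), c(0, 2))
  for (i in seq_len(S)) {
    src <- (perm[i] - 1L) * p + seq_len(p)
    dst <- (i - 1L) * p + seq_len(p)
    expect_equal(outp[, dst, ], out[, src, ], tolerance = 1e-9)
  }
})

test_that("parameter counts are reported and the MLP branch dominates", {
  counts <- vapply(c("unet_mlp", "unet_cnn", "unet_mlp_cnn", "transformer"),
                   function(a) denoiser_param_count(make_model(a)), 0)
  expect_true(all(counts > 0))
  expect_gt(counts[["unet_mlp"]], counts[["unet_cnn"]])
  expect_gt(counts[["unet_mlp_cnn"]], counts[["unet_mlp"]])
})
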