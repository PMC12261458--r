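test_that("the linear schedule has the closed-form cumulative products", {
  s1 <- noise_schedule(1, 0.5, 0.5)
  expect_equal(s1$alpha_bar, 0.5)

  s <- noise_schedule(1000, 1e-4, 0.02)
  expect_true(all(diff(s$alpha_bar) < 0))        # strictly decreasing
  expect_gte(s$alpha_bar[1], 1 - 2 * s$beta[1])  # starts near 1

  sc <- noise_schedule(10, 0.1, 0.1)
  expect_equal(sc$alpha_bar[10], 0.9^10, tolerance = 1e-12)

  expect_error(noise_schedule(10, 0.5, 0.2), "beta")
  expect_error(noise_schedule(0), "at least 1")
})

test_that("forward noising matches its closed-form marginal", {
  set.seed(61)
  mask <- matrix(rbinom(32, 1, 0.7), 4, 8)
  x0 <- random_clamped(2, mask, seed = 62)
  sched <- noise_schedule(100, 1e-3, 0.05)

  # zero-noise limit: alpha_bar ~ 1 at t = 1
  eps <- random_clamped(2, mask, seed = 63)
  xt1 <- forward_noise(x0, 1, eps, sched, mask)
  expect_equal(xt1, sqrt(sched$alpha_bar[1]) * x0 +
                 sqrt(1 - sched$alpha_bar[1]) * eps, tolerance = 1e-12)

  # Monte-Carlo: per live slot, Var(x_t) ~ (1 - alpha_bar_t) at fixed x0
  t_mid <- 60L
  n_draw <- 10000L
  x0_rep <- array(rep(x0[1, , ], each = n_draw), c(n_draw, 4, 8))
  set.seed(64)
  eps_mc <- apply_clamp(array(rnorm(n_draw * 32), c(n_draw, 4, 8)), mask)
  xt <- forward_noise(x0_rep, t_mid, eps_mc, sched, mask)
  v <- apply(xt, c(2, 3), stats::var)
  live <- mask == 1
  expect_true(all(abs(v[live] / (1 - sched$alpha_bar[t_mid]) - 1) < 0.05))
  expect_true(all(v[!live] == 0))

  expect_error(forward_noise(x0, 200, eps, sched, mask), "out of")
  expect_error(forward_noise(x0, 1, eps[, 1:2, , drop = FALSE], sched, mask),
               "shape")
})

test_that("the training loss is calibrated and decreases on a 2-gene toy", {
  set.seed(65)
  mask <- matrix(0, 8, 8); mask[1, 1:3] <- 1; mask[2, 1:2] <- 1
  sched <- noise_schedule(50)
  m <- denoiser("unet_mlp", G_pad = 8, n_classes = 2, depth = 1, seed = 66)
  # a zero-parameter transformer predicts exactly 0 (the U-Nets do not:
  # their additive input skip passes x_t through), so its loss is
  # E[eps^2] ~ 1 over live slots
  mz <- denoiser("transformer", G_pad = 8, n_classes = 2, patch = 4,
                 d_model = 8, n_layers = 1, seed = 66)
  mz$params <- lapply(mz$params, function(p) p * 0)
  batch <- random_clamped(64, mask, seed = 67)
  expect_equal(max(abs(denoiser_predict(mz, batch, 0.5))), 0)
  losses <- replicate(10, training_step(mz, batch, NULL, sched, mask)$loss)
  expect_lt(abs(mean(losses) - 1), 0.1)

  # 200 steps of Adam reduce the loss on a structured toy problem
  gd <- asNamespace("genodiff")
  x <- random_clamped(64, mask, seed = 68) * 0.2
  x[, 1, 1] <- rep(c(-2, 2), each = 32)       # two clusters
  x <- apply_clamp(x, mask)
  emb <- gene_embedding(x, mask, labels = rep(c(0, 1), each = 32))
  fit <- train_denoiser(m, emb, sched, steps = 200, batch_size = 16,
                        log_every = 50, seed = 69)
  expect_lt(tail(fit$log$train_loss, 1), fit$log$train_loss[1])
  expect_true(all(is.finite(fit$log$val_loss)))
})

test_that("ancestral sampling respects the clamp, the seed, and the T=1 closed form", {
  set.seed(70)
  mask <- matrix(rbinom(64, 1, 0.6), 8, 8)
  sched <- noise_schedule(30)
  m <- denoiser("unet_mlp", G_pad = 8, n_classes = 2, depth = 1, seed = 71)
  s1 <- sample_embeddings(m, 5, y = c(0, 1, 0, 1, 0), sched, mask, seed = 72)
  s2 <- sample_embeddings(m, 5, y = c(0, 1, 0, 1, 0), sched, mask, seed = 72)
  expect_identical(s1$tensor, s2$tensor)                  # determinism
  expect_identical(apply_clamp(s1$tensor, mask), s1$tensor)
  # padded slots exactly zero
  flat <- matrix(s1$tensor, 5, 64)
  expect_true(all(flat[, as.vector(mask) == 0] == 0))

  # T = 1 with an oracle noise predictor: output equals the posterior mean
  # formula (x_1 - beta_1/sqrt(1-ab_1) * eps) / sqrt(alpha_1) with eps the
  # starting noise itself
  sT1 <- noise_schedule(1, 0.3, 0.3)
  captured <- new.env()
  oracle <- function(x, t, y) { captured$x <- x; x }  # predicts eps = x_1
  out <- sample_embeddings(oracle, 3, NULL, sT1, mask, seed = 73)
  x1 <- captured$x
  manual <- (x1 - sT1$beta[1] / sqrt(1 - sT1$alpha_bar[1]) * x1) /
    sqrt(sT1$alpha[1])
  expect_equal(out$tensor, apply_clamp(manual, mask), tolerance = 1e-12)

  expect_error(sample_embeddings(m, 0, NULL, sched, mask), "positive")
})

test_that("one-shot reconstruction inverts exactly under an oracle predictor", {
  set.seed(74)
  mask <- matrix(rbinom(64, 1, 0.7), 8, 8)
  sched <- noise_schedule(40)
  x0 <- random_clamped(6, mask, seed = 75)
  eps <- random_clamped(6, mask, seed = 76)

  oracle <- function(x, t, y) eps          # knows the true noise
  r <- one_shot_reconstruct(oracle, x0, 25, sched, mask, epsilon = eps)
  expect_equal(r$x_p, x0, tolerance = 1e-10)
  expect_lt(r$error, 1e-10)

  # zero predictor at small t: x_p = x_t / sqrt(ab), so the residual is
  # sqrt((1-ab)/ab) * eps over live slots
  zero_model <- function(x, t, y) x * 0
  rz <- one_shot_reconstruct(zero_model, x0, 2, sched, mask, epsilon = eps)
  ab <- sched$alpha_bar[2]
  expected <- mean(sqrt(rowSums(
    genodiff:::flatten_batch(sqrt((1 - ab) / ab) * eps)^2)))
  expect_equal(rz$error, expected, tolerance = 1e-8)

  # padded slots contribute nothing to the error
  x0_dirty <- x0
  r2 <- one_shot_reconstruct(oracle, x0_dirty, 25, sched, mask, epsilon = eps)
  expect_lt(r2$error, 1e-10)
  expect_error(one_shot_reconstruct(oracle, x0, 99, sched, mask), "out of")
})
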