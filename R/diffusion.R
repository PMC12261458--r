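#' Build a linear noise schedule
#'
#' Standard denoising-diffusion forward process: `T` steps with linearly
#' spaced variances `beta_t`, signal retention `alpha_t = 1 - beta_t` and
#' cumulative products `alpha_bar_t`. Generation always runs all `T`
#' ancestral steps — no step skipping.
#'
#' @param T_steps number of diffusion steps.
#' @param beta_start,beta_end variance range, `0 < beta_start <= beta_end < 1`.
#' @return an object of class `noise_schedule`.
#' @export
noise_schedule <- function(T_steps = 1000, beta_start = 1e-4, beta_end = 0.02) {
  gd_assert(T_steps >= 1, "T must be at least 1")
  gd_assert(beta_start > 0 && beta_end < 1 && beta_start <= beta_end,
            "need 0 < beta_start <= beta_end < 1")
  beta <- seq(beta_start, beta_end, length.out = T_steps)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  structure(list(T = as.integer(T_steps), beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar, schedule_kind = "linear"),
            class = "noise_schedule")
}

#' @exportS3Method base::print
print.noise_schedule <- function(x, ...) {
  cat(sprintf("noise_schedule: linear, T=%d, beta in [%g, %g], alpha_bar_T=%.4g\n",
              x$T, x$beta[1], x$beta[x$T], x$alpha_bar[x$T]))
  invisible(x)
}

#' Apply the forward noising process
#'
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * epsilon`,
#' clamped so padded slots stay exactly zero.
#'
#' @param x0 clean tensor `n x G_pad x 8`.
#' @param t integer step(s) in `[1, T]`, length 1 or n.
#' @param epsilon noise tensor, same shape as `x0`.
#' @param schedule a [noise_schedule()].
#' @param clamp_mask binary `G_pad x 8` mask.
#' @return noised tensor, same shape.
#' @export
forward_noise <- function(x0, t, epsilon, schedule, clamp_mask) {
  gd_assert(all(dim(x0) == dim(epsilon)), "x0 and epsilon shapes differ")
  gd_assert(all(t >= 1 & t <= schedule$T), "t out of [1, T]")
  n <- dim(x0)[1]
  ab <- schedule$alpha_bar[rep_len(t, n)]
  m0 <- flatten_batch(x0)
  me <- flatten_batch(epsilon)
  xt <- sqrt(ab) * m0 + sqrt(1 - ab) * me
  apply_clamp(array(xt, dim(x0)), clamp_mask)
}

# standard-normal noise at live slots only, zero at padded slots
draw_clamped_noise <- function(n, clamp_mask) {
  G <- nrow(clamp_mask)
  eps <- array(rnorm(n * G * 8), c(n, G, 8))
  apply_clamp(eps, clamp_mask)
}

#' One gradient step of the epsilon-prediction objective
#'
#' Draws per-sample uniform steps `t`, clamped standard-normal noise, forms
#' `x_t`, and returns the masked mean-squared error between the drawn noise
#' and the model prediction, together with parameter gradients.
#'
#' @param model a [denoiser()].
#' @param batch tensor `B x G_pad x 8`, already clamped.
#' @param labels class labels (0-based) or NULL.
#' @param schedule a [noise_schedule()].
#' @param clamp_mask binary `G_pad x 8` mask.
#' @return list with `loss` (finite scalar) and `grads`.
#' @export
training_step <- function(model, batch, labels, schedule, clamp_mask) {
  B <- dim(batch)[1]
  t_int <- sample.int(schedule$T, B, replace = TRUE)
  eps <- draw_clamped_noise(B, clamp_mask)
  xt <- forward_noise(batch, t_int, eps, schedule, clamp_mask)
  tape <- ad_tape()
  nodes <- ad_param_nodes(tape, model$params)
  out <- denoiser_forward(tape, model, nodes, ad_const(tape, flatten_batch(xt)),
                          t_int / schedule$T, labels, B)
  mask_rows <- matrix(rep(as.vector(clamp_mask), each = B), B)
  loss_node <- ad_mse_masked(tape, out, flatten_batch(eps), mask_rows)
  loss <- loss_node$value[1]
  gd_assert(is.finite(loss),
            "non-finite training loss (t range ", min(t_int), "-", max(t_int), ")")
  ad_backward(tape, loss_node)
  list(loss = loss, grads = ad_collect_grads(nodes, model$params))
}

#' Train a denoiser on an embedding set
#'
#' Minibatch Adam on the epsilon-prediction loss. A validation split is
#' held out and the validation loss plus the one-shot reconstruction error
#' on a fixed `t` grid are logged at intervals, giving the usual training
#' curves.
#'
#' @param model a [denoiser()].
#' @param embedding a [gene_embedding()] of training data.
#' @param schedule a [noise_schedule()].
#' @param steps number of gradient steps.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param conditional use the embedding's labels as conditioning.
#' @param val_fraction fraction of samples held out for the training log.
#' @param log_every logging interval in steps.
#' @param recon_t one-shot reconstruction steps for the log (defaults to
#'   `0.25 T`, `0.5 T`, `0.75 T`).
#' @param seed RNG seed for batching, noise and initial validation noise.
#' @return list with the trained `model` and a `log` data.frame
#'   (step, train_loss, val_loss, recon_error).
#' @export
train_denoiser <- function(model, embedding, schedule, steps = 2000,
                           batch_size = 16, lr = 1e-3, conditional = TRUE,
                           val_fraction = 0.1, log_every = 100,
                           recon_t = NULL, seed = 1L) {
  x <- embedding$tensor
  mask <- embedding$clamp_mask
  labels <- if (conditional) embedding$labels else NULL
  n <- dim(x)[1]
  if (is.null(recon_t)) recon_t <- pmax(1L, as.integer(schedule$T * c(.25, .5, .75)))
  with_local_seed(seed, {
    n_val <- max(2L, round(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    xval <- x[val_idx, , , drop = FALSE]
    yval <- if (conditional) labels[val_idx] else NULL
    state <- adam_init(model$params)
    log <- data.frame(step = integer(), train_loss = numeric(),
                      val_loss = numeric(), recon_error = numeric())
    running <- numeric(0)
    for (s in seq_len(steps)) {
      bi <- tr_idx[sample.int(length(tr_idx), min(batch_size, length(tr_idx)))]
      batch <- x[bi, , , drop = FALSE]
      yb <- if (conditional) labels[bi] else NULL
      st <- training_step(model, batch, yb, schedule, mask)
      upd <- adam_step(model$params, st$grads, state, lr = lr)
      model$params <- upd$params
      state <- upd$state
      running <- c(running, st$loss)
      if (s %% log_every == 0 || s == steps) {
        vl <- validation_loss(model, xval, yval, schedule, mask)
        re <- mean(vapply(recon_t, function(tt)
          one_shot_reconstruct(model, xval, tt, schedule, mask, y = yval)$error,
          0))
        log <- rbind(log, data.frame(step = s, train_loss = mean(running),
                                     val_loss = vl, recon_error = re))
        running <- numeric(0)
      }
    }
    list(model = model, log = log)
  })
}

# deterministic validation loss: per-sample fixed t spread over [1, T]
validation_loss <- function(model, xval, yval, schedule, clamp_mask) {
  B <- dim(xval)[1]
  t_int <- pmax(1L, as.integer(round(seq(1, schedule$T, length.out = B))))
  eps <- draw_clamped_noise(B, clamp_mask)
  xt <- forward_noise(xval, t_int, eps, schedule, clamp_mask)
  pred <- denoiser_predict(model, xt, t_int / schedule$T, yval)
  nlive <- sum(clamp_mask) * B
  sum((apply_clamp(pred - eps, clamp_mask))^2) / nlive
}

#' Generate embeddings by ancestral sampling
#'
#' Starts from clamped standard-normal noise and runs all `T` reverse steps
#' (posterior mean from the epsilon prediction, posterior variance
#' `beta_tilde_t`), re-applying the clamp mask after every step so padded
#' slots are exactly zero in the output.
#'
#' @param model a trained [denoiser()].
#' @param n number of samples to draw.
#' @param y class label(s) (0-based, length 1 or n) or NULL.
#' @param schedule a [noise_schedule()].
#' @param clamp_mask binary `G_pad x 8` mask of the codec layout.
#' @param seed RNG seed; the same seed reproduces the tensors bit for bit.
#' @return a [gene_embedding()] of `n` samples.
#' @export
sample_embeddings <- function(model, n, y, schedule, clamp_mask, seed = 1L) {
  gd_assert(n >= 1, "n must be positive")
  if (!is.null(y)) y <- rep_len(y, n)
  with_local_seed(seed, {
    x <- draw_clamped_noise(n, clamp_mask)
    for (t in seq(schedule$T, 1L)) {
      eps_hat <- denoiser_predict(model, x, t / schedule$T, y)
      ab <- schedule$alpha_bar[t]
      mean_t <- (x - schedule$beta[t] / sqrt(1 - ab) * eps_hat) /
        sqrt(schedule$alpha[t])
      if (t > 1L) {
        ab_prev <- schedule$alpha_bar[t - 1L]
        sigma <- sqrt((1 - ab_prev) / (1 - ab) * schedule$beta[t])
        x <- mean_t + sigma * draw_clamped_noise(n, clamp_mask)
      } else {
        x <- mean_t
      }
      x <- apply_clamp(x, clamp_mask)
    }
    gene_embedding(x, clamp_mask,
                   labels = if (is.null(y)) integer(n) else y,
                   sample_ids = sprintf("SYN%05d", seq_len(n)))
  })
}

#' One-shot reconstruction at a fixed noise level
#'
#' Noises `x0` to step `t`, then inverts in a single step using the model's
#' noise prediction:
#' `x_p = (x_t - sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_bar_t)`,
#' clamped. The reconstruction error is the Euclidean norm of `x0 - x_p`
#' over live slots, averaged per sample.
#'
#' @param model a [denoiser()] (or any object usable by
#'   [denoiser_predict()]).
#' @param x0 clean tensor `n x G_pad x 8`.
#' @param t integer step in `[1, T]`.
#' @param schedule a [noise_schedule()].
#' @param clamp_mask binary mask.
#' @param y optional labels.
#' @param epsilon optional fixed noise (for oracle tests); drawn if NULL.
#' @return list with `x_p` and `error`.
#' @export
one_shot_reconstruct <- function(model, x0, t, schedule, clamp_mask,
                                 y = NULL, epsilon = NULL) {
  gd_assert(t >= 1 && t <= schedule$T, "t out of [1, T]")
  ab <- schedule$alpha_bar[t]
  gd_assert(ab > 0, "alpha_bar at t is zero; inversion undefined")
  n <- dim(x0)[1]
  if (is.null(epsilon)) epsilon <- draw_clamped_noise(n, clamp_mask)
  xt <- forward_noise(x0, t, epsilon, schedule, clamp_mask)
  eps_hat <- denoiser_predict(model, xt, t / schedule$T, y)
  xp <- apply_clamp((xt - sqrt(1 - ab) * eps_hat) / sqrt(ab), clamp_mask)
  diff <- apply_clamp(x0 - xp, clamp_mask)
  err <- mean(sqrt(rowSums(flatten_batch(diff)^2)))
  list(x_p = xp, error = err)
}
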