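# Reverse-mode automatic differentiation over matrices.
#
# A tape records nodes in creation order; backward() walks the tape in
# reverse, accumulating gradients into every node that requires them. Values
# and gradients are plain base-R matrices, so all heavy lifting is BLAS.
# The op set is the minimum the denoiser and classifier architectures need:
# matmul, broadcast add, elementwise mul, activations, softmax, row
# normalisation, gather/scatter rows (drives 1D convolution via im2col,
# pooling and upsampling), reshape, cbind/rbind, and reductions.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 512L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$requires <- length(parents) > 0 &&
    any(vapply(parents, function(p) p$requires, TRUE))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd$id <- tape$n
  nd
}

ad_const <- function(tape, x) {
  nd <- ad_node(tape, as_mat(x))
  nd$requires <- FALSE
  nd
}

ad_param <- function(tape, x) {
  nd <- ad_node(tape, as_mat(x))
  nd$requires <- TRUE
  nd
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

ad_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar (1x1) node.
ad_backward <- function(tape, node) {
  gd_assert(all(dim(node$value) == c(1, 1)), "backward start must be scalar")
  node$grad <- matrix(1, 1, 1)
  for (i in seq(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd) && !is.null(nd$backward) && !is.null(nd$grad) && nd$requires)
      nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- arithmetic ----------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, crossprod(a$value, g))
  })
}

# a + b; b may be a 1 x ncol row vector (broadcast over rows) or 1x1 scalar.
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (all(dim(av) == dim(bv))) {
    ad_node(tape, av + bv, list(a, b), function(g) {
      ad_accum(a, g); ad_accum(b, g)
    })
  } else if (nrow(bv) == 1 && ncol(bv) == ncol(av)) {
    ad_node(tape, av + rep(bv, each = nrow(av)), list(a, b), function(g) {
      ad_accum(a, g)
      ad_accum(b, matrix(colSums(g), 1))
    })
  } else if (all(dim(bv) == c(1, 1))) {
    ad_node(tape, av + bv[1], list(a, b), function(g) {
      ad_accum(a, g)
      ad_accum(b, matrix(sum(g), 1, 1))
    })
  } else gd_stop("ad_add: incompatible shapes")
}

# elementwise product; either operand may be a 1x1 scalar node
ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (all(dim(av) == dim(bv))) {
    ad_node(tape, av * bv, list(a, b), function(g) {
      ad_accum(a, g * bv); ad_accum(b, g * av)
    })
  } else if (all(dim(bv) == c(1, 1))) {
    ad_node(tape, av * bv[1], list(a, b), function(g) {
      ad_accum(a, g * bv[1])
      ad_accum(b, matrix(sum(g * av), 1, 1))
    })
  } else if (all(dim(av) == c(1, 1))) {
    ad_mul(tape, b, a)
  } else gd_stop("ad_mul: incompatible shapes")
}

# multiply every row of a by the matching entry of column node s (n x 1)
ad_mul_rows <- function(tape, a, s) {
  sv <- s$value
  gd_assert(ncol(sv) == 1 && nrow(sv) == nrow(a$value),
            "ad_mul_rows: s must be n x 1")
  ad_node(tape, a$value * sv[, 1], list(a, s), function(g) {
    ad_accum(a, g * sv[, 1])
    ad_accum(s, matrix(rowSums(g * a$value), ncol = 1))
  })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(g) ad_accum(a, g * k))
}

ad_addc <- function(tape, a, k) {
  ad_node(tape, a$value + k, list(a), function(g) ad_accum(a, g))
}

## ---- activations ---------------------------------------------------------

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, list(a), function(g) ad_accum(a, g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  th <- tanh(a$value)
  ad_node(tape, th, list(a), function(g) ad_accum(a, g * (1 - th^2)))
}

ad_relu <- function(tape, a) {
  m <- a$value > 0
  ad_node(tape, a$value * m, list(a), function(g) ad_accum(a, g * m))
}

ad_silu <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, a$value * s, list(a), function(g)
    ad_accum(a, g * (s + a$value * s * (1 - s))))
}

ad_softmax_rows <- function(tape, a) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(g)
    ad_accum(a, s * (g - rowSums(g * s))))
}

# row-wise standardisation (layer-norm core): (x - mean) / sd, sd with eps
ad_normalize_rows <- function(tape, a, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  ad_node(tape, xhat, list(a), function(g) {
    gm <- rowMeans(g)
    gx <- rowMeans(g * xhat)
    ad_accum(a, inv * (g - gm - xhat * gx))
  })
}

## ---- structure -----------------------------------------------------------

ad_reshape <- function(tape, a, nr, nc) {
  d <- dim(a$value)
  ad_node(tape, matrix(a$value, nr, nc), list(a), function(g)
    ad_accum(a, matrix(g, d[1], d[2])))
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(g) ad_accum(a, t(g)))
}

# select rows (with repetition); backward scatter-adds via rowsum()
ad_gather_rows <- function(tape, a, idx) {
  nr <- nrow(a$value)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nr, ncol(g))
    full[as.integer(rownames(acc)), ] <- acc
    ad_accum(a, full)
  })
}

# mean of rows within each group (groups must be 1..ngroups, all present)
ad_group_mean <- function(tape, a, group, ngroups) {
  counts <- tabulate(group, ngroups)
  gd_assert(all(counts > 0), "ad_group_mean: empty group")
  val <- rowsum(a$value, group) / counts
  ad_node(tape, val, list(a), function(g)
    ad_accum(a, g[group, , drop = FALSE] / counts[group]))
}

ad_cols <- function(tape, a, jset) {
  nc <- ncol(a$value)
  ad_node(tape, a$value[, jset, drop = FALSE], list(a), function(g) {
    full <- matrix(0, nrow(g), nc)
    full[, jset] <- full[, jset] + g
    ad_accum(a, full)
  })
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), 0L)
  ad_node(tape, do.call(cbind, lapply(nodes, `[[`, "value")), nodes,
          function(g) {
            off <- 0L
            for (k in seq_along(nodes)) {
              ad_accum(nodes[[k]], g[, off + seq_len(widths[k]), drop = FALSE])
              off <- off + widths[k]
            }
          })
}

ad_rbind <- function(tape, nodes) {
  heights <- vapply(nodes, function(n) nrow(n$value), 0L)
  ad_node(tape, do.call(rbind, lapply(nodes, `[[`, "value")), nodes,
          function(g) {
            off <- 0L
            for (k in seq_along(nodes)) {
              ad_accum(nodes[[k]], g[off + seq_len(heights[k]), , drop = FALSE])
              off <- off + heights[k]
            }
          })
}

## ---- reductions & losses -------------------------------------------------

ad_sum <- function(tape, a) {
  d <- dim(a$value)
  ad_node(tape, matrix(sum(a$value), 1, 1), list(a), function(g)
    ad_accum(a, matrix(g[1], d[1], d[2])))
}

ad_mean <- function(tape, a) {
  ad_scale(tape, ad_sum(tape, a), 1 / length(a$value))
}

# masked mean-squared error: sum(((pred - target) * mask)^2) / sum(mask)
ad_mse_masked <- function(tape, pred, target, mask) {
  d <- pred$value - target
  nlive <- sum(mask)
  ad_node(tape, matrix(sum((d * mask)^2) / nlive, 1, 1), list(pred),
          function(g) ad_accum(pred, g[1] * 2 * d * mask / nlive))
}

# mean cross-entropy of row-logits against 1-based class indices
ad_cross_entropy <- function(tape, logits, y) {
  z <- logits$value - apply(logits$value, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  nll <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  ad_node(tape, matrix(nll, 1, 1), list(logits), function(g) {
    gr <- p
    gr[cbind(seq_len(n), y)] <- gr[cbind(seq_len(n), y)] - 1
    ad_accum(logits, g[1] * gr / n)
  })
}

## ---- parameters & optimiser ----------------------------------------------

# turn a named list of parameter matrices into leaf nodes
ad_param_nodes <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

# collect gradients after backward(); unused parameters get zero gradients
ad_collect_grads <- function(nodes, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    g <- nodes[[nm]]$grad
    out[[nm]] <- if (is.null(g)) params[[nm]] * 0 else g
  }
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Glorot-uniform initialiser for a fan_in x fan_out weight
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

zeros_row <- function(n) matrix(0, 1, n)
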