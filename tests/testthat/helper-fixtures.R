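# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (double loops, full eigendecompositions)
# and never call the code paths they check.

tiny_cohort <- function(n = 120, genes = 12, seed = 5, ...) {
  cc <- cohort_config(n_samples = n, n_genes = genes,
                      snps_per_gene = c(5, 20), rank_range = c(2, 4),
                      n_causal = max(1, genes %/% 3), effect_size = 2,
                      prevalence = 0.4, seed = seed, ...)
  simulate_cohort(cc)
}

tiny_embedding <- function(n = 60, genes = 16, seed = 5, depth = 2) {
  co <- tiny_cohort(n, genes, seed)
  codec <- fit_gene_codec(co$genotypes, co$map, depth = depth)
  list(emb = encode_genotypes(co$genotypes, codec), codec = codec,
       cohort = co)
}

# brute-force nearest-neighbour adversarial accuracy (double loop)
oracle_nnaa <- function(A, B, metric = "l2") {
  d <- function(u, v) switch(metric,
    l2 = sqrt(sum((u - v)^2)),
    l1 = sum(abs(u - v)),
    cosine = {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) 1 else 1 - sum(u * v) / (nu * nv)
    })
  aa <- function(X, Y) {
    hits <- 0
    for (i in seq_len(nrow(X))) {
      d_cross <- min(vapply(seq_len(nrow(Y)),
                            function(j) d(X[i, ], Y[j, ]), 0))
      d_within <- min(vapply(setdiff(seq_len(nrow(X)), i),
                             function(j) d(X[i, ], X[j, ]), 0))
      if (d_cross > d_within) hits <- hits + 1
    }
    hits / nrow(X)
  }
  list(AA_truth = aa(A, B), AA_syn = aa(B, A))
}

# brute-force minimum cross-set distances (double loop)
oracle_min_distances <- function(A, B) {
  best <- c(l1 = Inf, l2 = Inf, cosine = Inf)
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      u <- A[i, ]; v <- B[j, ]
      best["l1"] <- min(best["l1"], sum(abs(u - v)))
      best["l2"] <- min(best["l2"], sqrt(sum((u - v)^2)))
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      cd <- if (nu == 0 || nv == 0) 1 else 1 - sum(u * v) / (nu * nv)
      best["cosine"] <- min(best["cosine"], cd)
    }
  }
  best
}

# independent PC-count rule: full eigendecomposition + cumulative-sum scan
oracle_pc_count <- function(X, threshold = 0.99, cap = 8) {
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) == 0) return(1L)
  r <- which(cumsum(ev) / sum(ev) >= threshold - 1e-12)[1]
  min(max(r, 1L), cap, ncol(X), nrow(X) - 1L)
}

# a combined-architecture model with lambda(t) pinned to a constant
pinned_lambda_model <- function(model, value) {
  stopifnot(model$config$arch == "unet_mlp_cnn")
  model$params$lam_W2[] <- 0
  model$params$lam_b2[] <- if (value == 0) -50 else if (value == 1) 50 else
    log(value / (1 - value))
  model
}

random_clamped <- function(n, mask, seed = 1) {
  set.seed(seed)
  apply_clamp(array(rnorm(n * nrow(mask) * 8), c(n, nrow(mask), 8)), mask)
}
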