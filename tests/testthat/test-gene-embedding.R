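test_that("gene-axis padding returns the smallest power-of-two multiple", {
  expect_equal(pad_gene_axis(2048, 11), 2048L)
  expect_equal(pad_gene_axis(100, 3), 104L)
  expect_equal(pad_gene_axis(1, 0), 1L)
  # padding never adds a full block
  set.seed(31)
  for (i in 1:50) {
    G <- sample(1:5000, 1); d <- sample(0:11, 1)
    P <- pad_gene_axis(G, d)
    expect_true(P >= G && P %% 2^d == 0 && P - G < 2^d)
  }
  expect_error(pad_gene_axis(0, 3), "positive")
})

test_that("PC-count rule matches an independent eigen-spectrum scan", {
  # rank-1 gene: all columns proportional
  base <- rnorm(30)
  X1 <- outer(base, c(1, 2, -1))
  ev1 <- svd(scale(X1, scale = FALSE), nu = 0)$d^2 / 29
  expect_equal(choose_pc_count(ev1, 3, 30), 1L)

  # full-rank gene stays within both caps
  set.seed(32)
  X5 <- matrix(rnorm(200), 40, 5)
  ev5 <- svd(scale(X5, scale = FALSE), nu = 0)$d^2 / 39
  r5 <- choose_pc_count(ev5, 5, 40)
  expect_lte(r5, 5); expect_lte(r5, 8); expect_gte(r5, 1)

  # random 40-SNP genes vs the brute-force oracle
  for (i in 1:10) {
    n <- 60
    X <- matrix(rnorm(n * 40), n, 40) %*% matrix(rnorm(40 * 40, sd = 0.5), 40)
    ev <- svd(scale(X, scale = FALSE), nu = 0)$d^2 / (n - 1)
    expect_equal(choose_pc_count(ev, 40, n, 0.99),
                 oracle_pc_count(X, 0.99))
  }
  expect_equal(choose_pc_count(rep(0, 5), 5, 100), 1L)  # constant gene
})

test_that("codec fitting recovers planted ranks and is sample-order invariant", {
  co <- simulate_cohort(cohort_config(n_samples = 250, n_genes = 12,
                                      snps_per_gene = c(6, 25),
                                      rank_range = c(2, 4),
                                      mutation_rate = 0, seed = 33))
  codec <- fit_gene_codec(co$genotypes, co$map, depth = 2, threshold = 0.999)
  # genotype columns are spanned by the k founder patterns of the gene
  for (g in seq_len(codec$G))
    expect_lte(codec$genes[[g]]$r, co$structure$ranks[g])

  # permuting samples leaves components unchanged (sign convention fixed)
  set.seed(1)
  perm <- sample(nrow(co$genotypes$values))
  co_p <- subset_genotypes(co$genotypes, perm)
  codec_p <- fit_gene_codec(co_p, co$map, depth = 2, threshold = 0.999)
  for (g in seq_len(codec$G))
    expect_equal(codec_p$genes[[g]]$components, codec$genes[[g]]$components,
                 tolerance = 1e-8)

  # component rows are orthonormal
  for (g in seq_len(codec$G)) {
    C <- codec$genes[[g]]$components
    if (sum(C^2) > 0)
      expect_equal(C %*% t(C), diag(nrow(C)), tolerance = 1e-8)
  }

  # constant gene: mean equals the column values, r = 1
  const <- genotype_matrix(matrix(1L, 10, 5), sprintf("s%d", 1:10),
                           data.frame(chrom = "1", pos = 1:5,
                                      ref = "A", alt = "C"))
  cmap <- gene_map(data.frame(gene_id = "g", chrom = "1",
                              start = 0, end = 100),
                   rep(1L, 5))
  ccodec <- fit_gene_codec(const, cmap, depth = 0)
  expect_equal(ccodec$genes[[1]]$mean, rep(1, 5))
  expect_equal(ccodec$genes[[1]]$r, 1L)
  expect_equal(genotype_mismatch(const, decode_embedding(
    encode_genotypes(const, ccodec), ccodec)), 0)
})

test_that("encode projects onto components exactly (hand matrix oracle)", {
  # 1 gene, 4 SNPs, 6 samples
  set.seed(34)
  vals <- matrix(sample(0:2, 24, replace = TRUE), 6, 4)
  gm <- genotype_matrix(vals, sprintf("s%d", 1:6),
                        data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "C"))
  map <- gene_map(data.frame(gene_id = "g", chrom = "1", start = 0, end = 50),
                  rep(1L, 4))
  codec <- fit_gene_codec(gm, map, depth = 0, threshold = 1)
  emb <- encode_genotypes(gm, codec)
  cd <- codec$genes[[1]]
  manual <- sweep(vals, 2, colMeans(vals)) %*% t(cd$components)
  expect_equal(matrix(emb$tensor[, 1, seq_len(cd$r)], 6), manual,
               tolerance = 1e-10)

  # centring contract: the training-set mean encodes to zero live slots,
  # i.e. the encoded scores have column mean zero
  expect_equal(colMeans(matrix(emb$tensor[, 1, seq_len(cd$r)], 6)),
               rep(0, cd$r), tolerance = 1e-10)

  # padding contract: tensor is zero wherever the mask is zero
  expect_true(all(emb$tensor * rep(1 - as.vector(emb$clamp_mask),
                                   each = 6) == 0))
  # live slot count equals the sum of retained components
  expect_equal(sum(emb$clamp_mask), sum(vapply(codec$genes, `[[`, 0L, "r")))
})

test_that("decode inverts encode on planted-rank data and degrades gracefully", {
  fx <- tiny_embedding(n = 80, genes = 12, seed = 35)
  co <- fx$cohort
  # mutation-free cohort with threshold 0.999: exact round trip
  co0 <- simulate_cohort(cohort_config(n_samples = 100, n_genes = 10,
                                       snps_per_gene = c(5, 20),
                                       rank_range = c(2, 4),
                                       mutation_rate = 0, seed = 36))
  codec0 <- fit_gene_codec(co0$genotypes, co0$map, depth = 2, threshold = 0.999)
  dec0 <- decode_embedding(encode_genotypes(co0$genotypes, codec0), codec0)
  expect_equal(genotype_mismatch(co0$genotypes, dec0), 0)

  # all-zero embedding decodes to per-gene rounded means
  emb0 <- gene_embedding(array(0, dim(encode_genotypes(co0$genotypes,
                                                       codec0)$tensor)),
                         codec0$clamp_mask)
  decm <- decode_embedding(emb0, codec0)
  g1 <- codec0$genes[[1]]
  expect_equal(decm$values[1, g1$snp_cols],
               as.integer(pmin(pmax(round(g1$mean), 0), 2)))

  # mismatch is non-increasing in the explained-variance threshold
  mism <- vapply(c(0.8, 0.95, 0.999), function(th) {
    cd <- fit_gene_codec(co$genotypes, co$map, depth = 2, threshold = th)
    genotype_mismatch(co$genotypes,
                      decode_embedding(encode_genotypes(co$genotypes, cd), cd))
  }, 0)
  expect_true(all(diff(mism) <= 1e-12))

  # layout mismatches error
  expect_error(decode_embedding(emb0, fx$codec), "match")
})

test_that("clamp is a masked projection and is idempotent", {
  set.seed(37)
  mask <- matrix(rbinom(40, 1, 0.5), 5, 8)
  x <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
  expect_equal(apply_clamp(x, matrix(1, 5, 8)), x)
  expect_equal(apply_clamp(x, matrix(0, 5, 8)), x * 0)
  once <- apply_clamp(x, mask)
  expect_identical(apply_clamp(once, mask), once)
  expect_error(apply_clamp(x, matrix(1, 4, 8)), "mismatch")
})
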