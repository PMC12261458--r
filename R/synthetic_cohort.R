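#' Configuration for the cohort simulator
#'
#' The simulator emulates the statistical structure the pipeline assumes of
#' real genotype panels: genes spanning a handful to about a hundred SNP
#' sites, strong within-gene linkage (each gene carries only a few founder
#' haplotype patterns, so its SNP matrix has low effective rank), allele
#' frequency differentiation between populations, and a polygenic binary
#' label spread over many genes.
#'
#' @param n_samples number of individuals.
#' @param n_genes number of genes on the simulated chromosome.
#' @param snps_per_gene integer range (length 2) of SNP sites per gene.
#' @param rank_range integer range of founder haplotype patterns per gene;
#'   the planted per-gene latent rank, at most 8.
#' @param mutation_rate per-site probability that a copied founder pattern
#'   bit is flipped; the only source of within-gene rank excess.
#' @param maf_range range of ancestral per-site alternative allele
#'   frequencies used to draw founder patterns.
#' @param n_populations number of populations `K`.
#' @param fst differentiation parameter `F` in `[0,1)`: population-specific
#'   founder-pattern frequencies are drawn from a Dirichlet centred on the
#'   ancestral frequencies with concentration `(1-F)/F` (the
#'   Balding-Nichols construction applied to pattern frequencies); `F = 0`
#'   means no differentiation.
#' @param n_causal number of genes carrying disease effects.
#' @param effect_size scale of per-gene liability effects.
#' @param noise_sd standard deviation of the non-genetic liability noise.
#' @param prevalence fraction of cases in `(0,1)`.
#' @param ploidy_mode `"genotype"` or `"haplotype"`.
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   bit for bit.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 1000, n_genes = 200,
                          snps_per_gene = c(5, 100), rank_range = c(2, 8),
                          mutation_rate = 0.002, maf_range = c(0.05, 0.5),
                          n_populations = 1, fst = 0.1,
                          n_causal = max(1, round(n_genes / 3)),
                          effect_size = 1, noise_sd = 1, prevalence = 0.3,
                          ploidy_mode = c("genotype", "haplotype"),
                          seed = 1L) {
  ploidy_mode <- match.arg(ploidy_mode)
  gd_assert(n_samples >= 1 && n_genes >= 1, "counts must be positive")
  gd_assert(snps_per_gene[1] >= 1 && snps_per_gene[2] >= snps_per_gene[1],
            "snps_per_gene range must lie in [1, Inf)")
  gd_assert(rank_range[1] >= 1 && rank_range[2] <= 8,
            "planted rank must stay within [1, 8]")
  gd_assert(fst >= 0 && fst < 1, "fst must be in [0, 1)")
  gd_assert(prevalence > 0 && prevalence < 1, "prevalence must be in (0,1)")
  gd_assert(n_causal <= n_genes, "n_causal exceeds n_genes")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 snps_per_gene = as.integer(snps_per_gene),
                 rank_range = as.integer(rank_range),
                 mutation_rate = mutation_rate, maf_range = maf_range,
                 n_populations = as.integer(n_populations), fst = fst,
                 n_causal = as.integer(n_causal), effect_size = effect_size,
                 noise_sd = noise_sd, prevalence = prevalence,
                 ploidy_mode = ploidy_mode, seed = as.integer(seed)),
            class = "cohort_config")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the gene structure of a simulated cohort
#'
#' Draws gene sizes, non-overlapping ordered gene intervals with their SNP
#' positions, the founder haplotype patterns that plant each gene's latent
#' rank, ancestral pattern frequencies, per-pattern liability effects, and
#' the causal gene set.
#'
#' @param config a [cohort_config()].
#' @return list with `genes` (data.frame), `variants` (data.frame),
#'   `snp_to_gene`, and per-gene `patterns`, `ancestral_freq`,
#'   `pattern_effects`, `causal_genes`.
#' @export
generate_gene_structure <- function(config) {
  with_local_seed(config$seed, {
    G <- config$n_genes
    sizes <- sample(seq(config$snps_per_gene[1], config$snps_per_gene[2]),
                    G, replace = TRUE)
    ranks <- sample(seq(config$rank_range[1], config$rank_range[2]),
                    G, replace = TRUE)
    # consecutive intervals with a gap; SNPs every ~10 bp inside the gene
    starts <- integer(G); ends <- integer(G)
    cursor <- 1000L
    pos <- integer(0); snp_to_gene <- integer(0)
    patterns <- vector("list", G)
    ancestral <- vector("list", G)
    effects <- vector("list", G)
    for (g in seq_len(G)) {
      s <- sizes[g]
      starts[g] <- cursor
      ends[g] <- cursor + 10L * s
      p_g <- cursor + 10L * (seq_len(s) - 1L) + 5L
      pos <- c(pos, p_g)
      snp_to_gene <- c(snp_to_gene, rep(g, s))
      cursor <- ends[g] + 200L
      maf <- runif(s, config$maf_range[1], config$maf_range[2])
      k <- min(ranks[g], 2^s)          # tiny genes cannot host many patterns
      pat <- matrix(rbinom(k * s, 1, rep(maf, each = k)), k, s)
      # founder patterns must be distinct so the planted rank is real
      tries <- 0
      while (anyDuplicated(pat) && tries < 50) {
        dup <- which(duplicated(pat))
        pat[dup, ] <- rbinom(length(dup) * s, 1, rep(maf, each = length(dup)))
        tries <- tries + 1
      }
      patterns[[g]] <- pat
      w <- runif(k, 0.5, 1.5)
      ancestral[[g]] <- w / sum(w)
      effects[[g]] <- rnorm(k)
    }
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(G)),
                        chrom = "1", start = starts, end = ends,
                        stringsAsFactors = FALSE)
    variants <- data.frame(chrom = "1", pos = pos + 1L,   # 1-based, VCF style
                           ref = "A", alt = "C", stringsAsFactors = FALSE)
    causal <- sort(sample(G, config$n_causal))
    list(genes = genes, variants = variants, snp_to_gene = snp_to_gene,
         patterns = patterns, ancestral_freq = ancestral,
         pattern_effects = effects, causal_genes = causal,
         sizes = sizes, ranks = ranks)
  })
}

# Draw population-specific pattern frequencies (Dirichlet around ancestral).
population_pattern_freqs <- function(structure, K, fst) {
  lapply(structure$ancestral_freq, function(a) {
    if (fst == 0 || K == 1) {
      matrix(a, K, length(a), byrow = TRUE)
    } else {
      conc <- (1 - fst) / fst
      f <- matrix(0, K, length(a))
      for (p in seq_len(K)) {
        gam <- rgamma(length(a), shape = a * conc)
        if (sum(gam) == 0) gam <- a
        f[p, ] <- gam / sum(gam)
      }
      f
    }
  })
}

# One haplotype row per draw: copy a founder pattern per gene, then flip
# bits at the mutation rate. pattern_choice is n_hap x G.
haplotypes_from_patterns <- function(structure, pattern_choice, mutation_rate) {
  n_hap <- nrow(pattern_choice)
  n_snps <- length(structure$snp_to_gene)
  H <- matrix(0L, n_hap, n_snps)
  col0 <- 0L
  for (g in seq_along(structure$patterns)) {
    s <- ncol(structure$patterns[[g]])
    H[, col0 + seq_len(s)] <- structure$patterns[[g]][pattern_choice[, g], ,
                                                      drop = FALSE]
    col0 <- col0 + s
  }
  if (mutation_rate > 0) {
    flips <- matrix(rbinom(n_hap * n_snps, 1, mutation_rate), n_hap)
    H <- abs(H - flips)
  }
  storage.mode(H) <- "integer"
  H
}

draw_pattern_choices <- function(structure, pop, freqs) {
  n <- length(pop)
  G <- length(structure$patterns)
  choice <- matrix(0L, n, G)
  for (g in seq_len(G)) {
    f <- freqs[[g]]
    for (p in unique(pop)) {
      idx <- which(pop == p)
      choice[idx, g] <- sample.int(ncol(f), length(idx), replace = TRUE,
                                   prob = f[p, ])
    }
  }
  choice
}

#' Simulate a haplotype cohort with population labels
#'
#' Each sample row is one phased chromosome copy in `{0,1}`; labels are
#' population indices `0..K-1`. Rows come in consecutive pairs per
#' individual, so summing row `2i-1` and `2i` yields that individual's
#' genotype.
#'
#' @param config a [cohort_config()] (its `ploidy_mode` is ignored; output
#'   is always haplotype mode).
#' @param structure optional, a [generate_gene_structure()] result to reuse.
#' @return list with `haplotypes` (a [genotype_matrix()]), `map`
#'   (a [gene_map()]), `structure`, and `pattern_choice`.
#' @export
generate_haplotypes <- function(config, structure = NULL) {
  if (is.null(structure)) structure <- generate_gene_structure(config)
  with_local_seed(config$seed + 101L, {
    K <- config$n_populations
    n <- config$n_samples
    pop <- sample.int(K, n, replace = TRUE)
    freqs <- population_pattern_freqs(structure, K, config$fst)
    hap_pop <- rep(pop, each = 2)
    choice <- draw_pattern_choices(structure, hap_pop, freqs)
    H <- haplotypes_from_patterns(structure, choice, config$mutation_rate)
    ids <- as.vector(rbind(sprintf("S%05d_A", seq_len(n)),
                           sprintf("S%05d_B", seq_len(n))))
    gm <- genotype_matrix(H, ids, structure$variants,
                          labels = hap_pop - 1L, ploidy_mode = "haplotype")
    map <- gene_map(structure$genes, structure$snp_to_gene)
    list(haplotypes = gm, map = map, structure = structure,
         pattern_choice = choice, population = pop)
  })
}

#' Assign polygenic disease labels to a simulated cohort
#'
#' Liability is the sum, over the causal genes, of the per-pattern effects
#' carried by the individual's two haplotypes, scaled by
#' `effect_size / sqrt(n_causal)`, plus Gaussian noise. Labels threshold the
#' liability at the prevalence quantile. The Bayes-optimal accuracy of the
#' generating model (classifying from the genetic liability alone) is
#' returned alongside.
#'
#' @param structure a [generate_gene_structure()] result.
#' @param pattern_choice haplotype-level pattern draws (2n x G).
#' @param config a [cohort_config()].
#' @return list with `labels` (0 = control, 1 = case), `liability`,
#'   `genetic_liability`, `threshold`, `bayes_accuracy`.
#' @export
assign_disease_labels <- function(structure, pattern_choice, config) {
  gd_assert(nrow(pattern_choice) %% 2 == 0,
            "pattern_choice must hold two haplotype rows per individual")
  n <- nrow(pattern_choice) / 2
  with_local_seed(config$seed + 202L, {
    beta <- config$effect_size / sqrt(config$n_causal)
    gen <- numeric(n)
    for (g in structure$causal_genes) {
      e <- structure$pattern_effects[[g]][pattern_choice[, g]]
      gen <- gen + beta * (e[seq(1, 2 * n, 2)] + e[seq(2, 2 * n, 2)])
    }
    noise <- rnorm(n, 0, config$noise_sd)
    liab <- gen + noise
    thr <- as.numeric(quantile(liab, 1 - config$prevalence))
    labels <- as.integer(liab > thr)
    p_case <- 1 - pnorm((thr - gen) / config$noise_sd)
    bayes <- mean(pmax(p_case, 1 - p_case))
    list(labels = labels, liability = liab, genetic_liability = gen,
         threshold = thr, bayes_accuracy = bayes)
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper: gene structure, haplotypes, and — in genotype mode —
#' per-individual genotypes with polygenic disease labels. In haplotype mode
#' the result carries population labels instead.
#'
#' @param config a [cohort_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `map`, `structure`,
#'   and (genotype mode) `oracle` from [assign_disease_labels()].
#' @export
simulate_cohort <- function(config) {
  hap <- generate_haplotypes(config)
  if (config$ploidy_mode == "haplotype") {
    return(list(genotypes = hap$haplotypes, map = hap$map,
                structure = hap$structure, oracle = NULL,
                population = hap$population))
  }
  H <- hap$haplotypes$values
  n <- nrow(H) / 2
  geno <- H[seq(1, 2 * n, 2), , drop = FALSE] + H[seq(2, 2 * n, 2), , drop = FALSE]
  oracle <- assign_disease_labels(hap$structure, hap$pattern_choice, config)
  gm <- genotype_matrix(geno, sprintf("S%05d", seq_len(n)),
                        hap$structure$variants, labels = oracle$labels,
                        ploidy_mode = "genotype")
  list(genotypes = gm, map = hap$map, structure = hap$structure,
       oracle = oracle, population = hap$population)
}
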