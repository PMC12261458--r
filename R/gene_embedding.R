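#' Pad the gene axis to a power-of-two multiple
#'
#' U-Net style denoisers halve the gene axis `depth` times, so the number of
#' gene slots must be divisible by `2^depth`. Returns the smallest multiple
#' of `2^depth` that is at least `G`; the extra slots are all-zero padded
#' genes, clamped throughout training and generation.
#'
#' @param G gene count (positive).
#' @param depth number of halvings (non-negative integer).
#' @return padded gene-axis length.
#' @examples
#' pad_gene_axis(18279, 11)  # 18432
#' pad_gene_axis(26624, 11)  # 26624, already divisible
#' @export
pad_gene_axis <- function(G, depth) {
  gd_assert(length(G) == 1 && G >= 1, "gene count must be positive")
  gd_assert(depth >= 0, "depth must be non-negative")
  block <- 2^depth
  as.integer(block * ceiling(G / block))
}

#' Choose the number of principal components for one gene
#'
#' The smallest `r` whose cumulative explained variance reaches `threshold`,
#' clipped into `[1, min(8, s_g, n - 1)]`. A gene with an all-zero spectrum
#' (constant columns) keeps a single component.
#'
#' @param spectrum non-negative, non-increasing eigenvalue spectrum.
#' @param s_g SNP count of the gene.
#' @param n number of training samples.
#' @param threshold cumulative explained-variance target, default 0.99.
#' @return integer component count `r_g`.
#' @export
choose_pc_count <- function(spectrum, s_g, n, threshold = 0.99) {
  gd_assert(all(spectrum >= -1e-12), "spectrum must be non-negative")
  gd_assert(!is.unsorted(rev(spectrum), strictly = FALSE) ||
              all(diff(spectrum) <= 1e-8),
            "spectrum must be non-increasing")
  cap <- max(1L, min(8L, s_g, n - 1L))
  total <- sum(spectrum)
  if (total <= 0) return(1L)
  r <- which(cumsum(spectrum) / total >= threshold - 1e-12)[1]
  if (is.na(r)) r <- length(spectrum)
  as.integer(min(max(r, 1L), cap))
}

# Deterministic PCA sign: largest-|loading| entry positive per component.
# Ties on the magnitude (common for pattern-structured genes) resolve to the
# earliest tied position, with a tolerance so floating-point noise cannot
# flip the choice between runs.
fix_component_signs <- function(comp, tol = 1e-6) {
  for (i in seq_len(nrow(comp))) {
    a <- abs(comp[i, ])
    j <- which(a >= max(a) - tol)[1]
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  comp
}

#' Fit the per-gene PCA codec
#'
#' One principal component analysis per gene, fitted on that gene's SNP
#' columns of the training samples only. Each gene keeps between 1 and 8
#' components, selected by the cumulative explained-variance rule of
#' [choose_pc_count()]. The codec is frozen after fitting: synthetic and
#' held-out data are encoded with the training-set means and components.
#'
#' @param train a [genotype_matrix()] of training samples.
#' @param map a [gene_map()] covering the matrix's SNP columns.
#' @param depth gene-axis halvings the downstream denoiser performs
#'   (controls padding).
#' @param threshold explained-variance threshold for [choose_pc_count()].
#' @return an object of class `gene_codec`.
#' @export
fit_gene_codec <- function(train, map, depth = 3, threshold = 0.99) {
  gd_assert(inherits(train, "genotype_matrix"), "train must be a genotype_matrix")
  n <- nrow(train$values)
  gd_assert(n >= 2, "need at least 2 training samples to fit a codec")
  idx <- gene_snp_index(map)
  gd_assert(all(lengths(idx) >= 1), "gene map contains a gene with zero SNPs")
  G <- length(idx)
  genes <- vector("list", G)
  for (g in seq_len(G)) {
    X <- train$values[, idx[[g]], drop = FALSE]
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = 0)
    ev <- sv$d^2 / max(1, n - 1)
    r <- choose_pc_count(ev, ncol(X), n, threshold)
    comp <- t(sv$v[, seq_len(r), drop = FALSE])
    if (sum(ev) <= 0) comp <- matrix(0, 1, ncol(X))   # constant gene
    genes[[g]] <- list(mean = mu, components = fix_component_signs(comp),
                       r = nrow(comp), snp_cols = idx[[g]])
  }
  G_pad <- pad_gene_axis(G, depth)
  mask <- matrix(0, G_pad, 8)
  for (g in seq_len(G)) mask[g, seq_len(genes[[g]]$r)] <- 1
  out <- structure(list(genes = genes, G = G, G_pad = G_pad, depth = depth,
                        threshold = threshold, n_train = n,
                        ploidy_mode = train$ploidy_mode,
                        n_snps = ncol(train$values), clamp_mask = mask),
                   class = "gene_codec")
  attr(out, "variants") <- train$variants
  out
}

#' @exportS3Method base::print
print.gene_codec <- function(x, ...) {
  rs <- vapply(x$genes, `[[`, 0L, "r")
  cat(sprintf(
    "gene_codec: %d genes (padded to %d, depth %d), %d live slots, r in [%d, %d]\n",
    x$G, x$G_pad, x$depth, sum(rs), min(rs), max(rs)))
  invisible(x)
}

#' Encode a genotype matrix into the gene embedding space
#'
#' Per gene: centre the gene's SNP vector with the codec mean and project it
#' onto the retained components; the scores fill the first `r_g` of the
#' gene's 8 slots, the rest stay zero, and padded gene slots beyond `G` are
#' all zero. The result is an `n x G_pad x 8` tensor with its clamp mask.
#'
#' @param x a [genotype_matrix()] whose SNP layout matches the codec.
#' @param codec a [fit_gene_codec()] result.
#' @return an object of class `gene_embedding`.
#' @export
encode_genotypes <- function(x, codec) {
  gd_assert(inherits(codec, "gene_codec"), "codec must be a gene_codec")
  gd_assert(ncol(x$values) == codec$n_snps,
            "SNP count mismatch: matrix has ", ncol(x$values),
            ", codec expects ", codec$n_snps)
  n <- nrow(x$values)
  tensor <- array(0, c(n, codec$G_pad, 8))
  for (g in seq_len(codec$G)) {
    cd <- codec$genes[[g]]
    Xc <- sweep(x$values[, cd$snp_cols, drop = FALSE], 2, cd$mean)
    tensor[, g, seq_len(cd$r)] <- Xc %*% t(cd$components)
  }
  gene_embedding(tensor, codec$clamp_mask, labels = x$labels,
                 sample_ids = x$sample_ids)
}

#' Construct a gene embedding object
#'
#' @param tensor numeric array `n x G_pad x 8`.
#' @param clamp_mask binary `G_pad x 8` matrix; 1 marks a live coefficient
#'   slot, 0 a padded slot that must stay exactly zero.
#' @param labels per-sample class indices.
#' @param sample_ids per-sample identifiers.
#' @return an object of class `gene_embedding`.
#' @export
gene_embedding <- function(tensor, clamp_mask,
                           labels = integer(dim(tensor)[1]),
                           sample_ids = sprintf("E%05d", seq_len(dim(tensor)[1]))) {
  gd_assert(length(dim(tensor)) == 3 && dim(tensor)[3] == 8,
            "tensor must be n x G_pad x 8")
  gd_assert(all(dim(clamp_mask) == dim(tensor)[2:3]),
            "clamp mask shape does not match tensor")
  tensor <- apply_clamp(tensor, clamp_mask)
  structure(list(tensor = tensor, clamp_mask = clamp_mask,
                 labels = as.integer(labels), sample_ids = sample_ids),
            class = "gene_embedding")
}

#' @exportS3Method base::print
print.gene_embedding <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("gene_embedding: %d samples x %d genes x 8 (%d live slots)\n",
              d[1], d[2], sum(x$clamp_mask)))
  invisible(x)
}

#' Zero out padded slots of an embedding tensor
#'
#' Multiplies every padded slot (clamp mask 0) to exactly zero and leaves
#' live slots untouched; idempotent. Applied after every diffusion step so
#' padded positions never accumulate noise.
#'
#' @param tensor `n x G_pad x 8` array (or `G_pad x 8` matrix for a single
#'   sample).
#' @param clamp_mask binary `G_pad x 8` matrix.
#' @return clamped tensor of the same shape.
#' @export
apply_clamp <- function(tensor, clamp_mask) {
  if (is.matrix(tensor)) {
    gd_assert(all(dim(tensor) == dim(clamp_mask)), "clamp mask shape mismatch")
    return(tensor * clamp_mask)
  }
  d <- dim(tensor)
  gd_assert(length(d) == 3 && all(d[2:3] == dim(clamp_mask)),
            "clamp mask shape mismatch")
  m <- matrix(tensor, d[1], d[2] * d[3])
  m <- m * rep(as.vector(clamp_mask), each = d[1])
  array(m, d)
}

#' Decode a gene embedding back to genotype calls
#'
#' Per gene: back-project the first `r_g` slots through the component
#' transpose, add the training mean, round to the nearest integer and clip
#' into the allele-count range ({0,1,2} for genotypes, {0,1} for
#' haplotypes). Padded genes are ignored.
#'
#' @param emb a [gene_embedding()].
#' @param codec the [fit_gene_codec()] used to encode.
#' @return a [genotype_matrix()].
#' @export
decode_embedding <- function(emb, codec) {
  gd_assert(inherits(emb, "gene_embedding"), "emb must be a gene_embedding")
  gd_assert(dim(emb$tensor)[2] == codec$G_pad,
            "embedding gene axis (", dim(emb$tensor)[2],
            ") does not match codec layout (", codec$G_pad, ")")
  gd_assert(all(emb$clamp_mask == codec$clamp_mask),
            "clamp mask does not match the codec layout")
  n <- dim(emb$tensor)[1]
  hi <- if (codec$ploidy_mode == "genotype") 2L else 1L
  vals <- matrix(0L, n, codec$n_snps)
  for (g in seq_len(codec$G)) {
    cd <- codec$genes[[g]]
    scores <- matrix(emb$tensor[, g, seq_len(cd$r)], n, cd$r)
    rec <- scores %*% cd$components + rep(cd$mean, each = n)
    vals[, cd$snp_cols] <- pmin(pmax(round(rec), 0L), hi)
  }
  storage.mode(vals) <- "integer"
  # decoded variant metadata mirrors the codec's column layout
  variants <- attr(codec, "variants")
  if (is.null(variants)) {
    variants <- data.frame(chrom = "1", pos = seq_len(codec$n_snps),
                           ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  genotype_matrix(vals, emb$sample_ids, variants, labels = emb$labels,
                  ploidy_mode = codec$ploidy_mode)
}

#' Fraction of mismatching genotype calls between two matrices
#'
#' @param a,b genotype matrices (or plain integer matrices) of equal shape.
#' @return scalar in `[0,1]`.
#' @export
genotype_mismatch <- function(a, b) {
  va <- if (inherits(a, "genotype_matrix")) a$values else a
  vb <- if (inherits(b, "genotype_matrix")) b$values else b
  gd_assert(all(dim(va) == dim(vb)), "shape mismatch")
  mean(va != vb)
}

#' Save / load a fitted codec
#'
#' Single-file archive holding per-gene means, components, retained counts
#' and the layout metadata.
#'
#' @param codec a `gene_codec`.
#' @param path file path.
#' @return `path` (save) or the codec (load).
#' @export
save_codec <- function(codec, path) {
  saveRDS(codec, path)
  invisible(path)
}

#' @rdname save_codec
#' @export
load_codec <- function(path) {
  codec <- readRDS(path)
  gd_assert(inherits(codec, "gene_codec"), "file does not hold a gene_codec")
  codec
}
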