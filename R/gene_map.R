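#' Construct a gene map
#'
#' Genes are kept in genomic order (chromosome, then start). Intervals are
#' 0-based, half-open `[start, end)` internally; 1-based variant positions
#' from VCF are converted before comparison.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param snp_to_gene integer vector, index into `genes` for every SNP.
#' @return an object of class `gene_map`.
#' @export
gene_map <- function(genes, snp_to_gene) {
  gd_assert(is.data.frame(genes) &&
              all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            "genes must have gene_id, chrom, start, end")
  gd_assert(all(genes$end > genes$start), "gene intervals must be non-empty")
  ord <- order(genes$chrom, genes$start)
  gd_assert(identical(ord, seq_len(nrow(genes))),
            "genes must be sorted in genomic order (chromosome, start)")
  snp_to_gene <- as.integer(snp_to_gene)
  gd_assert(all(snp_to_gene >= 1 & snp_to_gene <= nrow(genes)),
            "snp_to_gene indices out of range")
  # genes without SNPs are representable (an annotation can outnumber the
  # panel); the codec refuses them at fit time
  structure(list(genes = genes, snp_to_gene = snp_to_gene),
            class = "gene_map")
}

#' @exportS3Method base::print
print.gene_map <- function(x, ...) {
  counts <- tabulate(x$snp_to_gene, nrow(x$genes))
  cat(sprintf("gene_map: %d genes, %d SNPs (%d to %d SNPs per gene)\n",
              nrow(x$genes), length(x$snp_to_gene),
              min(counts), max(counts)))
  invisible(x)
}

#' Assign every SNP site to exactly one gene
#'
#' A SNP inside exactly one gene interval belongs to that gene. A SNP inside
#' several (overlapping) intervals goes to the containing gene whose midpoint
#' is nearest; a SNP inside no interval goes to the nearest gene on the same
#' chromosome by midpoint distance. Distance ties resolve to the gene earlier
#' in genomic order, so the assignment is deterministic.
#'
#' @param variants data.frame with `chrom` and 1-based `pos` (as returned in
#'   a [genotype_matrix()]), one row per SNP.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted in genomic order.
#' @return a [gene_map()].
#' @export
assign_snps_to_genes <- function(variants, genes) {
  ord <- order(genes$chrom, genes$start)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  pos0 <- variants$pos - 1L           # 1-based VCF -> 0-based
  assignment <- integer(nrow(variants))
  orphan_chroms <- setdiff(unique(variants$chrom), unique(genes$chrom))
  gd_assert(length(orphan_chroms) == 0,
            "SNP(s) on chromosome(s) with no genes: ",
            paste(orphan_chroms, collapse = ", "))
  for (ch in unique(variants$chrom)) {
    si <- which(variants$chrom == ch)
    gi <- which(genes$chrom == ch)
    p <- pos0[si]
    mid <- (genes$start[gi] + genes$end[gi]) / 2
    # best containing gene per SNP (nearest midpoint, earlier gene on ties)
    best <- rep(NA_integer_, length(si))
    best_d <- rep(Inf, length(si))
    for (j in seq_along(gi)) {
      inside <- p >= genes$start[gi[j]] & p < genes$end[gi[j]]
      d <- abs(p - mid[j])
      take <- inside & d < best_d     # strict: earlier gene wins ties
      best[take] <- j
      best_d[take] <- d[take]
    }
    out <- which(is.na(best))
    if (length(out)) {
      # nearest midpoint among all genes of the chromosome
      dmat_best <- rep(Inf, length(out))
      for (j in seq_along(gi)) {
        d <- abs(p[out] - mid[j])
        take <- d < dmat_best
        best[out][take] <- j
        dmat_best[take] <- d[take]
      }
    }
    assignment[si] <- gi[best]
  }
  gene_map(genes, assignment)
}

#' Read a BED-like gene map file
#'
#' Four whitespace-separated columns: chromosome, start, end, gene id
#' (0-based half-open coordinates, the BED convention). Rows are sorted into
#' genomic order.
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "gene_id"))
  df <- df[order(df$chrom, df$start), c("gene_id", "chrom", "start", "end")]
  rownames(df) <- NULL
  df
}

#' Write a gene map as BED
#' @param map a [gene_map()] or a genes data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(map, path) {
  genes <- if (inherits(map, "gene_map")) map$genes else map
  write.table(genes[, c("chrom", "start", "end", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# SNP column indices per gene, in gene order
gene_snp_index <- function(map) {
  split(seq_along(map$snp_to_gene), factor(map$snp_to_gene,
                                           levels = seq_len(nrow(map$genes))))
}
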