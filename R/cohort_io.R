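#' Construct a genotype matrix object
#'
#' The central data container: an integer matrix of allele counts
#' (samples x SNP sites), sample identifiers, variant metadata, per-sample
#' class labels, and the ploidy mode. In `"genotype"` mode entries are
#' diploid alternative-allele counts in `{0,1,2}`; in `"haplotype"` mode each
#' row is a single phased chromosome copy with entries in `{0,1}`.
#'
#' @param values integer matrix, samples in rows, SNP sites in columns.
#' @param sample_ids character vector, one id per row.
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, one row per SNP column.
#' @param labels integer vector of class indices in `0..K-1`, one per sample.
#' @param ploidy_mode `"genotype"` or `"haplotype"`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, sample_ids, variants,
                            labels = integer(nrow(values)),
                            ploidy_mode = c("genotype", "haplotype")) {
  ploidy_mode <- match.arg(ploidy_mode)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  dimnames(values) <- NULL
  gd_assert(nrow(values) >= 1, "genotype matrix must contain at least one sample")
  gd_assert(length(sample_ids) == nrow(values),
            "sample_ids length (", length(sample_ids),
            ") does not match sample count (", nrow(values), ")")
  gd_assert(length(labels) == nrow(values),
            "labels length does not match sample count")
  gd_assert(is.data.frame(variants) &&
              all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            "variants must be a data.frame with chrom, pos, ref, alt")
  gd_assert(nrow(variants) == ncol(values),
            "variant count (", nrow(variants),
            ") does not match SNP column count (", ncol(values), ")")
  hi <- if (ploidy_mode == "genotype") 2L else 1L
  bad <- which(is.na(values) | values < 0L | values > hi)
  gd_assert(length(bad) == 0,
            "genotype values outside {0..", hi, "} (or missing) at ",
            length(bad), " entries; first offender index ",
            if (length(bad)) bad[1] else "")
  # positions non-decreasing within chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    gd_assert(!is.unsorted(p),
              "variant positions not sorted on chromosome ", ch)
  }
  structure(
    list(values = values,
         sample_ids = as.character(sample_ids),
         variants = variants[, c("chrom", "pos", "ref", "alt")],
         labels = as.integer(labels),
         ploidy_mode = ploidy_mode),
    class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%s mode, %d classes)\n",
              nrow(x$values), ncol(x$values), x$ploidy_mode,
              length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

parse_variant_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  gd_assert(all(lengths(parts) == 4), "malformed variant id; expected chrom:pos:ref:alt")
  data.frame(chrom = vapply(parts, `[`, "", 1),
             pos = as.integer(vapply(parts, `[`, "", 2)),
             ref = vapply(parts, `[`, "", 3),
             alt = vapply(parts, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' Read a genotype matrix from disk
#'
#' Supports VCF v4.2 (GT field only, via the vcfR parser) and the package's
#' internal TSV dialect (first column `sample_id`, second column `label`,
#' remaining columns one per variant, named `chrom:pos:ref:alt`).
#'
#' For VCF in genotype mode, diploid calls map `0/0 -> 0`, `0/1` or
#' `1/0 -> 1`, `1/1 -> 2`. With `haplotypes = TRUE` every call must be
#' phased (`a|b`) and each sample is split into two haplotype rows
#' (`<id>_A`, `<id>_B`) with values in `{0,1}`. Multi-allelic sites and
#' missing calls are errors: no imputation is performed.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`.
#' @param haplotypes logical; split phased VCF calls into haplotype rows.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"), haplotypes = FALSE) {
  format <- match.arg(format)
  gd_assert(file.exists(path), "file not found: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path, haplotypes)
}

read_genotypes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  gd_assert(ncol(df) >= 3 && names(df)[1] == "sample_id" && names(df)[2] == "label",
            "internal TSV must start with sample_id and label columns")
  variants <- parse_variant_key(names(df)[-(1:2)])
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  genotype_matrix(vals, df$sample_id, variants, labels = df$label,
                  ploidy_mode = tsv_ploidy_mode(path))
}

# The TSV carries its ploidy mode in a '# ploidy_mode=' comment on line 1
# (values alone cannot distinguish an all-{0,1} genotype cohort from
# haplotypes).
tsv_ploidy_mode <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^#\\s*ploidy_mode=haplotype", first)) "haplotype" else "genotype"
}

read_genotypes_vcf <- function(path, haplotypes = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  gd_assert(!any(multi),
            "multi-allelic site(s): ",
            paste(fix[multi, "CHROM"], fix[multi, "POS"],
                  sep = ":", collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  n_snps <- nrow(gt)
  missing <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  gd_assert(!any(missing),
            "missing genotype call(s) at ", sum(missing),
            " entries; imputation is out of scope")
  labels <- vcf_labels_from_meta(vcf@meta, samples)
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  if (haplotypes) {
    phased <- grepl("|", gt, fixed = TRUE)
    gd_assert(all(phased), "unphased call(s) present; --haplotypes needs a|b calls")
    a1 <- matrix(as.integer(sub("\\|.*", "", gt)), n_snps)
    a2 <- matrix(as.integer(sub(".*\\|", "", gt)), n_snps)
    vals <- matrix(0L, 2 * length(samples), n_snps)
    vals[seq(1, by = 2, length.out = length(samples)), ] <- t(a1)
    vals[seq(2, by = 2, length.out = length(samples)), ] <- t(a2)
    ids <- as.vector(rbind(paste0(samples, "_A"), paste0(samples, "_B")))
    genotype_matrix(vals, ids, variants, labels = rep(labels, each = 2),
                    ploidy_mode = "haplotype")
  } else {
    alleles <- gsub("|", "/", gt, fixed = TRUE)
    a1 <- as.integer(sub("/.*", "", alleles))
    a2 <- as.integer(sub(".*/", "", alleles))
    gd_assert(!anyNA(a1) && !anyNA(a2), "malformed GT field in ", path)
    vals <- t(matrix(a1 + a2, n_snps))
    genotype_matrix(vals, samples, variants, labels = labels,
                    ploidy_mode = "genotype")
  }
}

vcf_labels_from_meta <- function(meta, samples) {
  line <- grep("^##genodiff_labels=", meta, value = TRUE)
  if (length(line) == 0) return(integer(length(samples)))
  as.integer(strsplit(sub("^##genodiff_labels=", "", line[1]), ",")[[1]])
}

#' Write a genotype matrix to disk
#'
#' Inverse of [read_genotypes()]: the written file reads back to an
#' identical matrix. TSV uses the internal dialect; VCF writes v4.2 with a
#' GT-only FORMAT. Haplotype matrices are written as phased VCF: consecutive
#' row pairs `(_A, _B)` become one diploid sample with `a|b` calls.
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  gd_assert(inherits(x, "genotype_matrix"), "x must be a genotype_matrix")
  gd_assert(nrow(x$values) >= 1, "refusing to write an empty sample list")
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ploidy_mode=", x$ploidy_mode), con)
    df <- data.frame(sample_id = x$sample_ids, label = x$labels,
                     x$values, check.names = FALSE)
    names(df)[-(1:2)] <- variant_key(x$variants)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  } else {
    write_genotypes_vcf(x, path)
  }
  invisible(path)
}

write_genotypes_vcf <- function(x, path) {
  if (x$ploidy_mode == "haplotype") {
    gd_assert(nrow(x$values) %% 2 == 0,
              "haplotype matrix needs an even number of rows to pair into samples")
    idx_a <- seq(1, nrow(x$values), by = 2)
    samples <- sub("_A$", "", x$sample_ids[idx_a])
    labels <- x$labels[idx_a]
    gts <- matrix(paste0(t(x$values[idx_a, , drop = FALSE]), "|",
                         t(x$values[idx_a + 1, , drop = FALSE])),
                  ncol(x$values))
  } else {
    samples <- x$sample_ids
    labels <- x$labels
    code <- c("0/0", "0/1", "1/1")
    gts <- matrix(code[t(x$values) + 1L], ncol(x$values))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##genodiff_labels=", paste(labels, collapse = ",")),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(x$variants$chrom, x$variants$pos, ".", x$variants$ref,
                x$variants$alt, ".", ".", ".", "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
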