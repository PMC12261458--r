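test_that("VCF genotype calls map to allele counts and haplotype splitting works", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
           "1\t100\t.\tA\tC\t.\t.\t.\tGT\t0|1\t1|1",
           "1\t200\t.\tG\tT\t.\t.\t.\tGT\t1|0\t0|0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)

  gm <- read_genotypes(path, "vcf")
  expect_equal(gm$values, matrix(c(1L, 2L, 1L, 0L), 2, 2))
  expect_equal(gm$ploidy_mode, "genotype")

  hap <- read_genotypes(path, "vcf", haplotypes = TRUE)
  expect_equal(nrow(hap$values), 4)
  expect_equal(hap$values[1, ], c(0L, 1L))   # S1 hap A
  expect_equal(hap$values[2, ], c(1L, 0L))   # S1 hap B
  expect_equal(hap$sample_ids[1:2], c("S1_A", "S1_B"))
  # the two haplotype rows sum to the genotype row
  expect_equal(hap$values[1, ] + hap$values[2, ], gm$values[1, ])
})

test_that("malformed inputs are rejected with informative errors", {
  base <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  multi <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(base, "1\t100\t.\tA\tC,G\t.\t.\t.\tGT\t0/1"), multi)
  expect_error(read_genotypes(multi, "vcf"), "multi-allelic")

  miss <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(base, "1\t100\t.\tA\tC\t.\t.\t.\tGT\t./."), miss)
  expect_error(read_genotypes(miss, "vcf"), "missing genotype")

  unphased <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(base, "1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/1"), unphased)
  expect_error(read_genotypes(unphased, "vcf", haplotypes = TRUE), "phased")

  expect_error(genotype_matrix(matrix(3L, 1, 1), "S1",
                               data.frame(chrom = "1", pos = 1,
                                          ref = "A", alt = "C")),
               "outside")
  expect_error(genotype_matrix(matrix(integer(0), 0, 0), character(0),
                               data.frame(chrom = character(0), pos = integer(0),
                                          ref = character(0), alt = character(0))),
               "at least one sample")
})

test_that("write/read round-trips are exact for both formats and modes", {
  co <- tiny_cohort(n = 30, genes = 6, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(co$genotypes, tsv, "tsv")
  rt <- read_genotypes(tsv, "tsv")
  expect_identical(rt$values, co$genotypes$values)
  expect_identical(rt$labels, co$genotypes$labels)
  expect_identical(rt$sample_ids, co$genotypes$sample_ids)
  expect_identical(rt$ploidy_mode, "genotype")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(co$genotypes, vcf, "vcf")
  rtv <- read_genotypes(vcf, "vcf")
  expect_identical(rtv$values, co$genotypes$values)
  expect_identical(rtv$labels, co$genotypes$labels)

  # haplotype cohort round-trips through phased VCF
  hc <- generate_haplotypes(cohort_config(n_samples = 15, n_genes = 4,
                                          snps_per_gene = c(5, 10), seed = 9))
  hvcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(hc$haplotypes, hvcf, "vcf")
  hrt <- read_genotypes(hvcf, "vcf", haplotypes = TRUE)
  expect_identical(hrt$values, hc$haplotypes$values)
  expect_identical(hrt$ploidy_mode, "haplotype")

  htsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(hc$haplotypes, htsv, "tsv")
  expect_identical(read_genotypes(htsv, "tsv")$ploidy_mode, "haplotype")
})

test_that("SNP-to-gene assignment follows containment and nearest-midpoint rules", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                      start = c(100, 250), end = c(200, 350))
  # pos is 1-based; internal coordinates are 0-based half-open
  v <- data.frame(chrom = "1", pos = c(151, 91, 200), ref = "A", alt = "C")
  map <- assign_snps_to_genes(v, genes)
  expect_equal(map$snp_to_gene[1], 1)   # inside [100,200)
  expect_equal(map$snp_to_gene[2], 1)   # outside; midpoints 150 vs 300
  expect_equal(map$snp_to_gene[3], 1)   # pos0 = 199, last contained base

  # overlapping genes: nearest midpoint, ties to the earlier gene
  og <- data.frame(gene_id = c("a", "b"), chrom = "1",
                   start = c(0, 40), end = c(100, 100))
  ov <- data.frame(chrom = "1", pos = c(61, 71), ref = "A", alt = "C")
  omap <- assign_snps_to_genes(ov, og)
  expect_equal(omap$snp_to_gene, c(1, 2))  # mids 50 and 70

  expect_error(assign_snps_to_genes(
    data.frame(chrom = "2", pos = 5, ref = "A", alt = "C"), genes),
    "no genes")
})

test_that("assignment matches a brute-force interval scan on random instances", {
  set.seed(71)
  for (rep in 1:20) {
    n_genes <- sample(2:10, 1)
    starts <- sort(sample(0:500, n_genes))
    genes <- data.frame(gene_id = paste0("g", seq_len(n_genes)), chrom = "1",
                        start = starts,
                        end = starts + sample(10:80, n_genes, replace = TRUE))
    pos <- sort(sample(1:600, sample(5:100, 1)))
    v <- data.frame(chrom = "1", pos = pos, ref = "A", alt = "C")
    map <- assign_snps_to_genes(v, genes)
    mids <- (genes$start + genes$end) / 2
    for (i in seq_along(pos)) {
      p0 <- pos[i] - 1
      inside <- which(genes$start <= p0 & p0 < genes$end)
      cand <- if (length(inside)) inside else seq_len(n_genes)
      d <- abs(mids[cand] - p0)
      expected <- cand[which(d == min(d))[1]]   # earlier gene wins ties
      expect_equal(map$snp_to_gene[i], expected)
    }
    expect_equal(sum(tabulate(map$snp_to_gene, n_genes)), length(pos))
  }
})
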