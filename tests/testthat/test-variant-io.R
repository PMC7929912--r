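test_that("VCF round-trip preserves genotypes, coordinates and alleles", {
  set.seed(11)
  mat <- rand_matrix(4, 30, miss_prob = 0.15)
  attr(mat, "contig_lengths") <- c(chr1 = 100000L, chr2 = 100000L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(mat, path)
  back <- read_vcf(path)
  expect_identical(unname(back$geno), unname(mat$geno))
  expect_identical(back$sites$chrom, mat$sites$chrom)
  expect_identical(back$sites$pos, mat$sites$pos)
  expect_identical(back$sample_ids, mat$sample_ids)
  expect_identical(attr(back, "contig_lengths"),
                   c(chr1 = 100000L, chr2 = 100000L))
  # second write of the re-read matrix is byte-identical
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("GT parsing handles phasing, missingness and shape", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1\t1|1",
    "chr1\t200\t.\tC\tG\t.\t.\t.\tGT\t./.\t./1",
    "chr1\t300\t.\tG\tA\t50\t.\t.\tGT:DP\t0/0:9\t1/0:7"),
    path)
  mat <- read_vcf(path)
  expect_equal(dim(mat), c(2L, 3L))
  expect_equal(unname(mat$geno["s1", ]), c(1L, NA, 0L))
  expect_equal(unname(mat$geno["s2", ]), c(2L, NA, 1L))
  expect_equal(mat$sites$qual, c(NA, NA, 50))
})

test_that("malformed VCF records raise errors naming the record", {
  base <- c("##fileformat=VCFv4.2",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(base, "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1/1"), path)
  expect_error(read_vcf(path), "non-diploid.*chr1\t100")
  writeLines(c(base,
               "chr1\t200\t.\tA\tT\t.\t.\t.\tGT\t0/1",
               "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_vcf(path), "unsorted.*chr1\t100")
  writeLines(c(base, "chr1\t100\t.\tA\tT\t.\t.\t.\tDP\t4"), path)
  expect_error(read_vcf(path), "GT")
})

test_that("empty matrices produce header-only VCFs that round-trip", {
  mat <- genotype_matrix(matrix(integer(0), nrow = 2, ncol = 0),
                         data.frame(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0)),
                         c("a", "b"))
  attr(mat, "contig_lengths") <- c(chr1 = 500L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(mat, path)
  expect_false(any(grepl("^[^#]", readLines(path))))
  back <- read_vcf(path)
  expect_equal(dim(back), c(2L, 0L))
})

test_that("popmap, contig-length and BED tables round-trip", {
  pm <- population_map(c("a", "b", "c"), c("p1", "p1", "p2"),
                       c("natural", "natural", "introduced"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  expect_equal(as.data.frame(read_popmap(path)), as.data.frame(pm))

  cl <- c(chr1 = 120000L, chr2 = 80000L)
  write_contig_lengths(cl, path)
  expect_identical(read_contig_lengths(path), cl)

  genes <- data.frame(chrom = "chr1", start = c(0L, 5000L),
                      end = c(1000L, 5400L), name = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_genes_bed(genes, bed)
  expect_equal(read_genes_bed(bed), genes)
})

test_that("population map validation catches bad input", {
  expect_error(population_map("a", "p1", "wild"), "category")
  expect_error(population_map(c("a", "a"), "p1", "natural"), "duplicate")
  pm <- population_map("a", "p1", "natural")
  mat <- rand_matrix(2, 5)
  expect_error(kelpscan:::check_popmap(pm, mat), "missing from population")
  expect_error(pop_samples(pm, "nope"), "not present")
  expect_equal(pop_samples(pm, "category:natural"), "a")
})

test_that("filter_variants applies rules in order with first-fail counting", {
  # 5-site toy: 1 indel, 1 triallelic, 1 low-MAF (1/40 = 0.025), 2 passing
  g <- rbind(rep(1L, 5), rep(1L, 5), c(0L, 0L, 0L, 1L, 0L),
             rep(0L, 5), rep(0L, 5),
             rep(0L, 5), rep(0L, 5), rep(0L, 5), rep(0L, 5), rep(0L, 5),
             rep(0L, 5), rep(0L, 5), rep(0L, 5), rep(0L, 5), rep(0L, 5),
             rep(0L, 5), rep(0L, 5), rep(0L, 5), rep(0L, 5), rep(0L, 5))
  g[, 3] <- 0L; g[1, 3] <- 1L  # site 3: single het -> MAF 1/40
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                      ref = c("A", "AT", "C", "G", "T"),
                      alt = c("T", "A", "G", "C,A", "G"),
                      stringsAsFactors = FALSE)
  mat <- genotype_matrix(g, sites, sprintf("s%02d", 1:20))
  res <- filter_variants(mat, maf_min = 0.05, max_missing = 0.2)
  expect_equal(res$report$input, 5L)
  expect_equal(res$report$retained, 2L)
  expect_equal(unname(res$report$removed[c("non_snp", "multi_allelic",
                                           "maf")]), c(1L, 1L, 1L))
  expect_equal(res$matrix$sites$pos, c(10L, 50L))
  expect_equal(res$report$input,
               res$report$retained + sum(res$report$removed))
})

test_that("filter_variants is idempotent and supports the no-op identity", {
  set.seed(4)
  mat <- rand_matrix(6, 40, miss_prob = 0.2)
  once <- filter_variants(mat, maf_min = 0.1, max_missing = 0.3)
  twice <- filter_variants(once$matrix, maf_min = 0.1, max_missing = 0.3)
  expect_identical(twice$matrix$geno, once$matrix$geno)
  expect_equal(twice$report$retained, twice$report$input)

  noop <- filter_variants(mat, snps_only = FALSE, biallelic_only = FALSE,
                          maf_min = 0, max_missing = 1)
  expect_identical(noop$matrix$geno, mat$geno)

  empty <- genotype_matrix(matrix(integer(0), 2, 0),
                           data.frame(chrom = character(0), pos = integer(0),
                                      ref = character(0),
                                      alt = character(0)), c("a", "b"))
  res <- filter_variants(empty)
  expect_equal(res$report$input, 0L)
  expect_equal(sum(res$report$removed), 0L)
})

test_that("window tilings partition the genome", {
  w <- make_windows(c(chrA = 120000L), 50000L)
  expect_equal(w$start, c(0L, 50000L, 100000L))
  expect_equal(w$end, c(50000L, 100000L, 120000L))
  expect_equal(nrow(make_windows(c(c1 = 50000L), 50000L)), 1L)
  expect_error(make_windows(c(c1 = 100L), 0), "positive")

  set.seed(9)
  for (i in 1:10) {
    lens <- setNames(sample.int(300000L, 3), c("a", "b", "c"))
    size <- sample.int(70000L, 1)
    w <- make_windows(lens, size)
    expect_equal(sum(w$end - w$start), sum(lens))
    by_chr <- split(w, w$chrom)
    for (ww in by_chr) {
      expect_true(all(ww$start < ww$end))
      expect_true(all(diff(ww$start) > 0))
      expect_true(all(ww$start[-1] == ww$end[-nrow(ww)])) # no gaps/overlap
    }
  }
})
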