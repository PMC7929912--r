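small_cfg <- function(seed = 1L, ...) {
  simulation_config(n_chromosomes = 1L, chrom_length_bp = 50000L,
                    ancestral_N = 100L, burn_in = 50L, generations = 30L,
                    sample_sizes = c(natural1 = 6L), selfing_rate = 0,
                    seed = seed, ...)
}

test_that("configuration validation rejects invalid worlds", {
  expect_error(simulation_config(mu = 2), "\\[0, 1\\]")
  expect_error(simulation_config(selfing_rate = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(founder_size = 1000, ancestral_N = 500),
               "founder_size")
  expect_error(simulation_config(sample_sizes = c(5L, 5L)), "named")
  expect_error(simulation_config(
    sweep_loci = data.frame(chrom = 1, pos = 1e9, s = 0.1)), "outside")
  expect_error(simulation_config(
    sweep_loci = data.frame(chrom = 9, pos = 100, s = 0.1)), "outside")
  expect_error(simulation_config(
    sample_sizes = c(natural1 = 4L),
    categories = c(natural1 = "farm")), "natural/cultivated/introduced")
  expect_error(simulation_config(
    sample_sizes = c(cultivated1 = 4L)), "at least one natural")
})

test_that("identical config and seed give bit-identical serialized output", {
  cfg <- small_cfg(seed = 123)
  sim1 <- simulate_populations(cfg)
  sim2 <- simulate_populations(small_cfg(seed = 123))
  expect_identical(sim1$matrix$geno, sim2$matrix$geno)
  expect_identical(sim1$matrix$sites, sim2$matrix$sites)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim1$matrix, f1); write_vcf(sim2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different world
  sim3 <- simulate_populations(small_cfg(seed = 124))
  expect_false(identical(sim1$matrix$geno, sim3$matrix$geno))
})

test_that("emitted matrices satisfy the structural contract", {
  cfg <- simulation_config(
    n_chromosomes = 2L, chrom_length_bp = 50000L, ancestral_N = 100L,
    burn_in = 50L, generations = 30L, selfing_rate = 0.2,
    intro_gens = 10L, founder_gens = 3L, intro_N = 20L,
    pool_generations = 3L, pool_N = 50L,
    sample_sizes = c(natural1 = 5L, natural2 = 4L,
                     cultivated1 = 5L, introduced1 = 6L),
    seed = 7L)
  sim <- simulate_populations(cfg)
  mat <- sim$matrix
  # sites sorted by (chromosome, position)
  same <- mat$sites$chrom[-1] == mat$sites$chrom[-nrow(mat$sites)]
  expect_true(all(diff(mat$sites$pos)[same] > 0))
  # population labels match the configured sample sizes
  counts <- table(sim$popmap$population)[names(cfg$sample_sizes)]
  expect_equal(as.integer(counts), unname(cfg$sample_sizes))
  expect_equal(sim$popmap$category,
               unname(cfg$categories[sim$popmap$population]))
  # monomorphic-in-sample sites are flagged, not dropped
  cs <- colSums(mat$geno)
  mono <- cs == 0 | cs == 2 * nrow(mat$geno)
  expect_identical(attr(mat, "monomorphic_in_sample"), mono)
  # all non-flagged sites have union-sample frequency strictly inside (0,1)
  expect_true(all(cs[!mono] > 0 & cs[!mono] < 2 * nrow(mat$geno)))
  # truth record
  expect_equal(sim$truth$theta, 4 * 100 * 1e-6)
  expect_true(all(c("ancestral", names(cfg$sample_sizes)) %in%
                    sim$truth$census$population))
})

test_that("truth tables round-trip through TSV", {
  sim <- simulate_populations(small_cfg(seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$theta, sim$truth$theta)
  expect_equal(back$sweeps, sim$truth$sweeps)
  expect_equal(back$census, sim$truth$census, ignore_attr = TRUE)
  # zero sweeps -> no sweep rows
  tab <- data.table::fread(path, sep = "\t")
  expect_equal(sum(tab$record == "sweep"), 0L)

  cfg <- simulation_config(
    n_chromosomes = 1L, chrom_length_bp = 50000L, ancestral_N = 100L,
    burn_in = 30L, generations = 60L, selfing_rate = 0,
    sweep_loci = data.frame(chrom = c(1L, 1L), pos = c(10000L, 30000L),
                            s = c(0.3, 0.3)),
    sweep_population = "natural1",
    sweep_max_gens = 150L, post_sweep_gens = 10L,
    sample_sizes = c(natural1 = 6L), seed = 5L)
  sim2 <- simulate_populations(cfg)
  expect_equal(nrow(sim2$truth$sweeps), 2L)
  expect_equal(sim2$truth$sweeps$pos, c(10000L, 30000L))
  write_truth(sim2$truth, path)
  expect_equal(read_truth(path)$sweeps, sim2$truth$sweeps)
})

test_that("higher selfing raises mean F_IS (rank-monotone over replicates)", {
  mean_fis <- function(selfing) {
    vals <- vapply(1:8, function(k) {
      cfg <- simulation_config(
        n_chromosomes = 4L, chrom_length_bp = 25000L, ancestral_N = 100L,
        burn_in = 60L, generations = 0L, selfing_rate = selfing,
        sample_sizes = c(natural1 = 10L), seed = 9000L + k)
      sim <- simulate_populations(cfg)
      group_summary(sim$matrix, sim$matrix$sample_ids, total_bp = 1e5)$fis
    }, numeric(1))
    mean(vals)
  }
  fis <- vapply(c(0, 0.5, 0.9), mean_fis, numeric(1))
  expect_true(all(diff(fis) > 0))
  expect_gt(fis[3], 0.2) # strong selfing is visibly inbred
})

test_that("re-introduction pulses keep the introduced population diverse", {
  base <- simulation_config(
    n_chromosomes = 2L, chrom_length_bp = 50000L, ancestral_N = 150L,
    burn_in = 80L, generations = 40L, selfing_rate = 0.2,
    founder_size = 3L, founder_gens = 5L, intro_N = 30L, intro_gens = 40L,
    sample_sizes = c(natural1 = 8L, introduced1 = 8L), seed = 31L)
  pulsed <- simulation_config(
    n_chromosomes = 2L, chrom_length_bp = 50000L, ancestral_N = 150L,
    burn_in = 80L, generations = 40L, selfing_rate = 0.2,
    founder_size = 3L, founder_gens = 5L, intro_N = 30L, intro_gens = 40L,
    n_reintroduction_pulses = 3L, pulse_fraction = 0.4,
    sample_sizes = c(natural1 = 8L, introduced1 = 8L), seed = 31L)
  pi_of <- function(cfg) {
    sim <- simulate_populations(cfg)
    group_summary(sim$matrix, pop_samples(sim$popmap, "introduced1"),
                  total_bp = 1e5)$pi
  }
  # repeated introductions replenish diversity relative to a single founding
  expect_gt(pi_of(pulsed), pi_of(base))
})

test_that("synthetic gene tracks tile the genome uniformly", {
  genes <- make_synthetic_genes(c(chr1 = 10000L, chr2 = 5000L),
                                gene_length = 1000L, spacing = 2500L)
  expect_true(all(genes$end - genes$start <= 1000L))
  expect_true(all(genes$start >= 0))
  expect_false(any(duplicated(genes$name)))
  expect_equal(sum(genes$chrom == "chr1"), 4L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_genes_bed(genes, path)
  expect_equal(read_genes_bed(path), genes)
})
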