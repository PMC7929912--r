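test_that("site_pi matches enumeration and handles degenerate counts", {
  expect_equal(site_pi(2, 4), 0.666667, tolerance = 1e-6)
  expect_equal(site_pi(2, 4), oracle_site_pi(2, 4))
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(10, 10), 0)
  expect_true(is.na(site_pi(1, 1)))
  expect_error(site_pi(5, 4), "between 0")
  # vectorised equals scalar oracle
  for (n in c(2, 5, 8)) for (j in 0:n)
    expect_equal(site_pi(j, n), oracle_site_pi(j, n), tolerance = 1e-12)
})

test_that("watterson_theta matches the harmonic-number form", {
  expect_equal(watterson_theta(3, 4, 100), 0.016364, tolerance = 1e-4)
  expect_equal(watterson_theta(0, 6, 100), 0)
  expect_equal(watterson_theta(5, 2, 100), 5 / 100) # a1 = 1
  expect_true(is.na(watterson_theta(3, 1, 100)))
  expect_equal(watterson_theta(7, 9, 250), oracle_theta_w(7, 9, 250))
})

test_that("window_pi sums site diversity over the window length", {
  mat <- genotype_matrix(
    matrix(c(1L, 1L, 1L, 1L), nrow = 2),
    data.frame(chrom = "chr1", pos = c(10L, 60L), ref = "A", alt = "T"),
    c("s1", "s2"))
  res <- window_pi(mat, list(chrom = "chr1", start = 0L, end = 100L),
                   c("s1", "s2"))
  expect_equal(res$pi, (2 / 3 + 2 / 3) / 100, tolerance = 1e-9)
  expect_equal(res$n_snps, 2L)
  # doubling the window length halves per-bp pi
  res2 <- window_pi(mat, list(chrom = "chr1", start = 0L, end = 200L),
                    c("s1", "s2"))
  expect_equal(res2$pi, res$pi / 2)
  # windows without variants give 0
  res3 <- window_pi(mat, list(chrom = "chr1", start = 100L, end = 200L),
                    c("s1", "s2"))
  expect_equal(res3$pi, 0)
})

test_that("tajimas_d reproduces the worked n=4 fixture and sign behaviour", {
  mat <- tajima_micro_fixture()
  w <- whole_window(mat)
  d <- tajimas_d(mat, w, mat$sample_ids)
  expect_equal(d, 1.090, tolerance = 1e-3)
  expect_equal(d, oracle_tajima_d(c(2, 2, 1), c(4, 4, 4)), tolerance = 1e-12)
  # no segregating sites -> MISSING, not zero
  mono <- genotype_matrix(matrix(0L, 2, 1),
                          data.frame(chrom = "chr1", pos = 5L,
                                     ref = "A", alt = "T"), c("s1", "s2"))
  expect_true(is.na(tajimas_d(mono, whole_window(mono), mono$sample_ids)))
  # all-singleton windows (excess rare variants) give D < 0
  g <- matrix(0L, 6, 8)
  g[1, ] <- 1L
  sing <- genotype_matrix(g, data.frame(chrom = "chr1",
                                        pos = seq(10L, 80L, by = 10L),
                                        ref = "A", alt = "T"),
                          sprintf("s%d", 1:6))
  expect_lt(tajimas_d(sing, whole_window(sing), sing$sample_ids), 0)
})

test_that("heterozygosity and F_IS follow the worked example", {
  mat <- genotype_matrix(matrix(1L, 4, 1),
                         data.frame(chrom = "chr1", pos = 10L,
                                    ref = "A", alt = "T"),
                         sprintf("s%d", 1:4))
  hh <- expected_observed_het(mat, whole_window(mat), mat$sample_ids)
  expect_equal(hh$ho, 1)
  expect_equal(hh$he, 2 * 0.25 * 8 / 7, tolerance = 1e-9) # 0.5714
  expect_equal(inbreeding_fis(hh$he, hh$ho), -0.75, tolerance = 1e-3)
  expect_equal(inbreeding_fis(0.4, 0.4), 0)
  expect_equal(inbreeding_fis(0.4, 0), 1)
  expect_true(is.na(inbreeding_fis(0, 0.1)))
  # monomorphic window -> MISSING pair
  mono <- genotype_matrix(matrix(0L, 4, 1),
                          data.frame(chrom = "chr1", pos = 10L,
                                     ref = "A", alt = "T"),
                          sprintf("s%d", 1:4))
  hh2 <- expected_observed_het(mono, whole_window(mono), mono$sample_ids)
  expect_true(is.na(hh2$he) && is.na(hh2$ho))
})

test_that("weir_cockerham_fst hits the boundary cases and the WC84 oracle", {
  # fixed difference -> 1
  g <- cbind(c(rep(0L, 10), rep(2L, 10)))
  mat <- genotype_matrix(g, data.frame(chrom = "chr1", pos = 50L,
                                       ref = "A", alt = "T"),
                         sprintf("s%02d", 1:20))
  w <- whole_window(mat)
  a <- mat$sample_ids[1:10]; b <- mat$sample_ids[11:20]
  expect_equal(weir_cockerham_fst(mat, w, a, b), 1)
  # identical sample sets -> approximately 0; the duplicated-group design
  # has an intrinsic small negative bias of about -1/(2n-2), so use n large
  # enough that |bias| stays well under the 0.05 check
  set.seed(21)
  freqs <- runif(40, 0.2, 0.8)
  hwe <- sapply(freqs, function(p) rbinom(16, 2, p))
  mm <- genotype_matrix(hwe,
                        data.frame(chrom = "chr1",
                                   pos = sort(sample.int(100000L, 40)),
                                   ref = "A", alt = "T"),
                        sprintf("s%02d", 1:16))
  ww <- list(chrom = "chr1", start = 0L, end = 100000L)
  self_fst <- weir_cockerham_fst(mm, ww, mm$sample_ids, mm$sample_ids)
  expect_lt(abs(self_fst), 0.05)
  # symmetry
  expect_equal(weir_cockerham_fst(mm, ww, mm$sample_ids[1:8],
                                  mm$sample_ids[9:16]),
               weir_cockerham_fst(mm, ww, mm$sample_ids[9:16],
                                  mm$sample_ids[1:8]))
  # one-site two-population fixture against the scalar WC84 oracle
  ga <- c(0L, 0L, 0L, 2L, 0L)  # freq 0.2, all hom
  gb <- c(2L, 2L, 2L, 0L, 2L)  # freq 0.8, all hom
  mat2 <- genotype_matrix(cbind(c(ga, gb)),
                          data.frame(chrom = "chr1", pos = 5L,
                                     ref = "A", alt = "T"),
                          sprintf("s%02d", 1:10))
  got <- weir_cockerham_fst(mat2, whole_window(mat2),
                            mat2$sample_ids[1:5], mat2$sample_ids[6:10])
  expect_equal(got, oracle_wc_fst(cbind(ga), cbind(gb)), tolerance = 1e-12)
})

test_that("rod and delta_tajima are simple oriented differences", {
  expect_equal(rod(0.001, 0.004), 0.75)
  expect_equal(rod(0.004, 0.004), 0)
  expect_equal(rod(0, 0.004), 1)
  expect_true(is.na(rod(0.001, 0)))
  expect_equal(delta_tajima(-1.2, 0.3), -1.5)
  expect_equal(delta_tajima(0.4, 0.4), 0)
  expect_true(is.na(delta_tajima(NA, 0.3)))
})

test_that("statistics are invariant to sample order and ref/alt swap", {
  set.seed(33)
  mat <- rand_matrix(8, 60, miss_prob = 0.1)
  w <- list(chrom = "chr1", start = 0L, end = 100000L)
  samp <- mat$sample_ids
  perm <- sample(samp)
  expect_equal(window_pi(mat, w, samp), window_pi(mat, w, perm))
  # ref/alt swap: genotype codes flip 0 <-> 2
  swapped <- genotype_matrix(2L - mat$geno, mat$sites, samp)
  expect_equal(window_pi(mat, w, samp)$pi, window_pi(swapped, w, samp)$pi)
  hh <- expected_observed_het(mat, w, samp)
  hh2 <- expected_observed_het(swapped, w, samp)
  expect_equal(hh$he, hh2$he)
  expect_equal(hh$ho, hh2$ho)
  expect_equal(weir_cockerham_fst(mat, w, samp[1:4], samp[5:8]),
               weir_cockerham_fst(swapped, w, samp[1:4], samp[5:8]))
})

test_that("windowed tables agree with per-window operations", {
  set.seed(55)
  mat <- rand_matrix(6, 80, miss_prob = 0.05)
  windows <- make_windows(c(chr1 = 100000L, chr2 = 100000L), 25000L)
  samp <- mat$sample_ids[1:4]
  tbl <- pop_window_stats(mat, windows, samp)
  expect_equal(nrow(tbl), nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    expect_equal(tbl$pi[i], window_pi(mat, w, samp)$pi, tolerance = 1e-12)
    expect_equal(tbl$tajima_d[i], tajimas_d(mat, w, samp),
                 tolerance = 1e-12)
  }
  pair <- pair_window_stats(mat, windows, mat$sample_ids[1:3],
                            mat$sample_ids[4:6])
  for (i in seq_len(nrow(windows))) {
    expect_equal(pair$fst[i],
                 weir_cockerham_fst(mat, windows[i, ], mat$sample_ids[1:3],
                                    mat$sample_ids[4:6]),
                 tolerance = 1e-12)
  }
  expect_equal(pair$rod, rod(pair$pi_focal, pair$pi_ref))
  expect_equal(pair$delta_d, delta_tajima(pair$d_focal, pair$d_ref))
})
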