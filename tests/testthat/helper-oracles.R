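# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: per-site scalar loops, explicit pair enumeration,
# and longhand transcriptions of the published estimator formulas.

# mean pairwise difference over all allele pairs drawn without replacement
oracle_site_pi <- function(j, n) {
  if (n < 2) return(NA_real_)
  alleles <- c(rep(1L, j), rep(0L, n - j))
  diffs <- 0L; pairs <- 0L
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    pairs <- pairs + 1L
    if (alleles[a] != alleles[b]) diffs <- diffs + 1L
  }
  diffs / pairs
}

oracle_theta_w <- function(S, n, L) {
  if (n < 2) return(NA_real_)
  a1 <- 0
  for (i in 1:(n - 1)) a1 <- a1 + 1 / i
  S / (a1 * L)
}

# Tajima (1989) D, written out longhand from the published constants
oracle_tajima_d <- function(j, nal) {
  seg <- j > 0 & j < nal
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  n <- round(mean(nal[seg]))
  if (n < 4) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  pi_sum <- 0
  for (k in which(seg)) pi_sum <- pi_sum + oracle_site_pi(j[k], nal[k])
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# per-site scalar He (unbiased), Ho and group allele counts from a genotype
# submatrix (rows = samples)
oracle_site_summary <- function(g) {
  g <- g[!is.na(g)]
  n_ind <- length(g)
  if (n_ind == 0) return(list(j = 0L, nal = 0L, he = NA, ho = NA))
  j <- sum(g)
  nal <- 2L * n_ind
  p <- j / nal
  list(j = j, nal = nal,
       he = 2 * p * (1 - p) * nal / (nal - 1),
       ho = sum(g == 1L) / n_ind)
}

# Weir & Cockerham (1984) theta-hat for two populations at one site,
# scalar transcription of equations (2)-(4) with r = 2
oracle_wc_site <- function(ga, gb) {
  ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
  n1 <- length(ga); n2 <- length(gb)
  if (n1 < 2 || n2 < 2) return(NULL)
  r <- 2
  p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
  h1 <- sum(ga == 1L) / n1; h2 <- sum(gb == 1L) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_fst <- function(GA, GB) {
  num <- 0; den <- 0; any_site <- FALSE
  for (k in seq_len(ncol(GA))) {
    comp <- oracle_wc_site(GA[, k], GB[, k])
    if (is.null(comp)) next
    any_site <- TRUE
    num <- num + comp[["a"]]
    den <- den + sum(comp)
  }
  if (!any_site || den == 0) return(NA_real_)
  num / den
}

# r^2 via explicit moment sums over complete pairs
oracle_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]; n <- length(x)
  sx <- sum(x); sy <- sum(y)
  vx <- sum(x^2) - sx^2 / n
  vy <- sum(y^2) - sy^2 / n
  if (vx == 0 || vy == 0) return(NA_real_)
  cxy <- sum(x * y) - sx * sy / n
  (cxy / sqrt(vx * vy))^2
}

# random small genotype matrix fixture
rand_matrix <- function(n_samples, n_sites, miss_prob = 0.1,
                        chroms = c("chr1", "chr2")) {
  g <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
              nrow = n_samples)
  if (miss_prob > 0)
    g[runif(length(g)) < miss_prob] <- NA_integer_
  chrom <- sort(sample(chroms, n_sites, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(cn)
    sort(sample.int(100000L, sum(chrom == cn)))), use.names = FALSE)
  genotype_matrix(g,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                             stringsAsFactors = FALSE),
                  sprintf("s%02d", seq_len(n_samples)))
}

# the worked Tajima's D micro-fixture: 2 diploids (n = 4 alleles), three
# segregating sites with alt-allele counts {2, 2, 1}
tajima_micro_fixture <- function() {
  genotype_matrix(
    geno = matrix(c(1L, 1L,   # alt count 2
                    2L, 0L,   # alt count 2
                    1L, 0L),  # alt count 1
                  nrow = 2),
    sites = data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                       ref = "A", alt = "T", stringsAsFactors = FALSE),
    sample_ids = c("s1", "s2"))
}

whole_window <- function(mat) {
  list(chrom = mat$sites$chrom[1], start = 0L,
       end = max(mat$sites$pos) + 1L)
}

# columns of ranks with pairwise Spearman correlation EXACTLY zero: hill-
# climbing pair swaps until each new permutation's dot product with every
# accepted column equals n(n+1)^2/4 (n must be divisible by 4)
orthogonal_rank_stats <- function(n, k = 3, seed = 1) {
  stopifnot(n %% 4 == 0)
  set.seed(seed)
  target <- n * (n + 1)^2 / 4
  cols <- list(seq_len(n))
  while (length(cols) < k) {
    y <- sample(n)
    for (iter in 1:20000) {
      devs <- vapply(cols, function(x) sum(x * y) - target, numeric(1))
      if (all(devs == 0)) break
      i <- sample(n, 1); j <- sample(n, 1)
      deltas <- vapply(cols, function(x) (x[i] - x[j]) * (y[j] - y[i]),
                       numeric(1))
      if (sum(abs(devs + deltas)) < sum(abs(devs))) {
        tmp <- y[i]; y[i] <- y[j]; y[j] <- tmp
      }
    }
    if (all(vapply(cols, function(x) sum(x * y), numeric(1)) == target))
      cols[[length(cols) + 1]] <- y
  }
  do.call(cbind, cols) + 0
}
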