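#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2 j (n - j) / (n (n - 1))` for `j` copies
#' of the alternate allele among `n` sampled alleles: the probability that two
#' alleles drawn without replacement differ.
#'
#' @param alt_count number of alternate alleles at the site (vectorised).
#' @param total_count total number of non-missing alleles.
#' @return per-site diversity; `NA` where `total_count < 2`.
#' @examples
#' site_pi(2, 4) # 2/3
#' @export
site_pi <- function(alt_count, total_count) {
  if (any(alt_count < 0 | alt_count > total_count, na.rm = TRUE))
    stop("alt_count must be between 0 and total_count")
  out <- 2 * alt_count * (total_count - alt_count) /
    (total_count * (total_count - 1))
  out[total_count < 2] <- NA_real_
  out
}

#' Watterson's theta per bp
#'
#' `S / (a1 * L)` with `a1` the harmonic number of `n_alleles - 1`.
#'
#' @param n_snps number of segregating sites S.
#' @param n_alleles sample size in alleles (2 x diploid count).
#' @param length_bp window length in bp.
#' @return per-bp estimate; `NA` if `n_alleles < 2`.
#' @examples
#' watterson_theta(3, 4, 100)
#' @export
watterson_theta <- function(n_snps, n_alleles, length_bp) {
  if (length(n_alleles) == 1 && (is.na(n_alleles) || n_alleles < 2))
    return(NA_real_)
  a1 <- vapply(n_alleles, function(n) {
    if (is.na(n) || n < 2) NA_real_ else sum(1 / seq_len(n - 1))
  }, numeric(1))
  n_snps / (a1 * length_bp)
}

# Tajima (1989) normalising constants for a sample of n alleles
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# per-site allele summaries for one sample group; sites with more than
# `max_missing_frac` missing genotypes in the group are masked (keep = FALSE)
group_site_stats <- function(mat, samples, max_missing_frac = 0.5) {
  G <- mat$geno[match(samples, mat$sample_ids), , drop = FALSE]
  if (anyNA(match(samples, mat$sample_ids)))
    stop("unknown sample(s) in group")
  n_nonmiss <- colSums(!is.na(G))
  nal <- 2L * n_nonmiss
  j <- colSums(G, na.rm = TRUE)
  keep <- (nrow(G) - n_nonmiss) / nrow(G) <= max_missing_frac & nal >= 2L
  p <- ifelse(nal > 0, j / nal, NA_real_)
  list(
    n_nonmiss = n_nonmiss, nal = nal, j = j, p = p, keep = keep,
    seg = j > 0L & j < nal,
    pi_site = site_pi(j, nal),
    he_site = ifelse(nal >= 2, 2 * p * (1 - p) * nal / (nal - 1), NA_real_),
    ho_site = ifelse(n_nonmiss > 0,
                     colSums(G == 1L, na.rm = TRUE) / n_nonmiss, NA_real_)
  )
}

# indices of matrix sites falling in a single window (0-based half-open)
sites_in_window <- function(mat, window) {
  which(mat$sites$chrom == window$chrom &
          mat$sites$pos - 1L >= window$start &
          mat$sites$pos - 1L < window$end)
}

#' Windowed nucleotide diversity
#'
#' Sum of [site_pi()] over in-window segregating sites divided by the full
#' window length in bp, so unlisted (invariant) positions contribute zero
#' diversity. Alleles are counted from non-missing genotypes only.
#'
#' @param mat a [genotype_matrix()].
#' @param window list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param samples sample ids of the group.
#' @return list with `pi` (per-bp) and `n_snps` (segregating sites used).
#' @export
window_pi <- function(mat, window, samples) {
  st <- group_site_stats(mat, samples)
  idx <- sites_in_window(mat, window)
  idx <- idx[st$keep[idx]]
  len <- window$end - window$start
  sel <- idx[st$seg[idx]]
  list(pi = if (length(sel)) sum(st$pi_site[sel]) / len else 0,
       n_snps = length(sel))
}

#' Tajima's D in a window
#'
#' Standard normalised difference between the pairwise estimator and
#' Watterson's estimator, with constants computed from the (rounded mean)
#' number of non-missing alleles at the window's segregating sites.
#' `NA` when there are no segregating sites or fewer than 4 alleles.
#'
#' @inheritParams window_pi
#' @return Tajima's D, or `NA`.
#' @export
tajimas_d <- function(mat, window, samples) {
  st <- group_site_stats(mat, samples)
  idx <- sites_in_window(mat, window)
  idx <- idx[st$keep[idx]]
  tajima_d_from_sites(st$j[idx], st$nal[idx])
}

# D from vectors of alt-allele counts and allele totals (segregating subset
# selected internally)
tajima_d_from_sites <- function(j, nal) {
  seg <- j > 0 & j < nal
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  n <- round(mean(nal[seg]))
  if (is.na(n) || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  pi_sum <- sum(site_pi(j[seg], nal[seg]))
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - S / k$a1) / sqrt(v)
}

#' Expected and observed heterozygosity in a window
#'
#' Per-site unbiased expected heterozygosity `2 p (1 - p) n/(n - 1)` and the
#' observed heterozygote fraction, averaged over in-window variant
#' (segregating) sites.
#'
#' @inheritParams window_pi
#' @return list with `he` and `ho`; both `NA` when the window has no variant
#'   site in the group.
#' @export
expected_observed_het <- function(mat, window, samples) {
  st <- group_site_stats(mat, samples)
  idx <- sites_in_window(mat, window)
  idx <- idx[st$keep[idx] & st$seg[idx]]
  if (!length(idx)) return(list(he = NA_real_, ho = NA_real_))
  list(he = mean(st$he_site[idx]), ho = mean(st$ho_site[idx]))
}

#' Inbreeding coefficient F_IS
#'
#' `1 - Ho/He`; elevated under selfing, negative under outbreeding excess.
#'
#' @param he expected heterozygosity (> 0).
#' @param ho observed heterozygosity.
#' @return F_IS, `NA` where `he` is 0 or missing.
#' @export
inbreeding_fis <- function(he, ho) {
  out <- 1 - ho / he
  out[!is.na(he) & he == 0] <- NA_real_
  out
}

# Weir & Cockerham (1984) per-site variance components for two groups.
# Returns vectors a, b, c and a validity mask; sites failing per-group
# missingness or with < 2 called individuals in either group are masked.
wc_components <- function(mat, samples_a, samples_b,
                          max_missing_frac = 0.5) {
  GA <- mat$geno[match(samples_a, mat$sample_ids), , drop = FALSE]
  GB <- mat$geno[match(samples_b, mat$sample_ids), , drop = FALSE]
  nA <- colSums(!is.na(GA)); nB <- colSums(!is.na(GB))
  ok <- nA >= 2 & nB >= 2 &
    (nrow(GA) - nA) / nrow(GA) <= max_missing_frac &
    (nrow(GB) - nB) / nrow(GB) <= max_missing_frac
  pA <- colSums(GA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(GB, na.rm = TRUE) / (2 * nB)
  hA <- colSums(GA == 1L, na.rm = TRUE) / nA
  hB <- colSums(GB == 1L, na.rm = TRUE) / nB
  nbar <- (nA + nB) / 2
  nc <- (nA + nB) - (nA^2 + nB^2) / (nA + nB)
  pbar <- (nA * pA + nB * pB) / (nA + nB)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / nbar
  hbar <- (nA * hA + nB * hB) / (nA + nB)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc, ok = ok)
}

#' Weir-Cockerham F_ST in a window
#'
#' Variance-component estimator theta-hat of Weir & Cockerham (1984),
#' aggregated over in-window sites as a ratio of sums
#' `sum(a) / sum(a + b + c)`.
#'
#' @inheritParams window_pi
#' @param pop_a_samples,pop_b_samples sample ids of the two groups.
#' @return F_ST estimate, or `NA` when no site is usable or the denominator
#'   is zero.
#' @export
weir_cockerham_fst <- function(mat, window, pop_a_samples, pop_b_samples) {
  comp <- wc_components(mat, pop_a_samples, pop_b_samples)
  idx <- sites_in_window(mat, window)
  idx <- idx[comp$ok[idx]]
  if (!length(idx)) return(NA_real_)
  den <- sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
  if (!is.finite(den) || den == 0) return(NA_real_)
  sum(comp$a[idx]) / den
}

#' Reduction of diversity
#'
#' `ROD = 1 - pi_focal / pi_reference`: positive when the focal population
#' (e.g. an introduced or cultivated group) has lost diversity relative to
#' the reference (baseline, typically natural) population.
#'
#' @param pi_focal,pi_reference per-bp diversities (vectorised).
#' @return ROD; `NA` where `pi_reference` is 0 or missing.
#' @export
rod <- function(pi_focal, pi_reference) {
  out <- 1 - pi_focal / pi_reference
  out[!is.na(pi_reference) & pi_reference == 0] <- NA_real_
  out
}

#' Delta Tajima's D
#'
#' Focal minus reference Tajima's D; strongly negative over sweeps in the
#' focal group. Missing inputs propagate.
#'
#' @param d_focal,d_reference Tajima's D values (vectorised).
#' @return difference, `NA` where either input is missing.
#' @export
delta_tajima <- function(d_focal, d_reference) d_focal - d_reference

#' Per-window within-population statistics
#'
#' Vectorised computation of the full within-group window table: segregating
#' site count, per-bp pi and Watterson's theta, Tajima's D, mean expected and
#' observed heterozygosity over variant sites, and F_IS (from the window-mean
#' heterozygosities).
#'
#' @param mat a [genotype_matrix()].
#' @param windows tiling from [make_windows()].
#' @param samples sample ids of the group.
#' @param max_missing_frac per-group site missingness mask (default 0.5).
#' @return data.frame, one row per window: `chrom`, `start`, `end`,
#'   `callable_bp` (the per-bp denominator; the full window span, since no
#'   callability mask is modelled), `n_snps`, `pi`, `theta_w`, `tajima_d`,
#'   `he`, `ho`, `fis`.
#' @export
pop_window_stats <- function(mat, windows, samples, max_missing_frac = 0.5) {
  st <- group_site_stats(mat, samples, max_missing_frac)
  widx <- window_index(windows, mat$sites$chrom, mat$sites$pos)
  use <- which(st$keep & !is.na(widx))
  n_win <- nrow(windows)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end,
                    callable_bp = windows$end - windows$start,
                    n_snps = 0L, pi = 0, theta_w = 0,
                    tajima_d = NA_real_, he = NA_real_, ho = NA_real_,
                    fis = NA_real_, stringsAsFactors = FALSE)
  if (!length(use)) return(out)
  dt <- data.table::data.table(
    w = widx[use], j = st$j[use], nal = st$nal[use], seg = st$seg[use],
    pi_site = st$pi_site[use], he_site = st$he_site[use],
    ho_site = st$ho_site[use])
  agg <- dt[, {
    s <- seg
    S <- sum(s)
    nmean <- if (S > 0) round(mean(nal[s])) else NA_real_
    list(n_snps = S,
         pi_sum = sum(pi_site[s]),
         theta = if (S > 0 && !is.na(nmean) && nmean >= 2)
           S / sum(1 / seq_len(nmean - 1)) else 0,
         tajd = tajima_d_from_sites(j, nal),
         he = if (S > 0) mean(he_site[s]) else NA_real_,
         ho = if (S > 0) mean(ho_site[s]) else NA_real_)
  }, by = "w"]
  len <- windows$end[agg$w] - windows$start[agg$w]
  out$n_snps[agg$w] <- agg$n_snps
  out$pi[agg$w] <- agg$pi_sum / len
  out$theta_w[agg$w] <- agg$theta / len
  out$tajima_d[agg$w] <- agg$tajd
  out$he[agg$w] <- agg$he
  out$ho[agg$w] <- agg$ho
  out$fis <- inbreeding_fis(out$he, out$ho)
  out
}

#' Per-window between-group statistics
#'
#' Weir-Cockerham F_ST (ratio of sums), reduction of diversity and delta
#' Tajima's D for a (focal, reference) pair of groups, per window.
#'
#' @inheritParams pop_window_stats
#' @param focal_samples,ref_samples sample ids of the focal and reference
#'   groups (ROD and delta-D are oriented focal vs reference).
#' @return data.frame, one row per window: coordinates plus `fst`, `rod`,
#'   `delta_d`, and the underlying `pi_focal`, `pi_ref`, `d_focal`, `d_ref`,
#'   `n_snps` (sites usable for F_ST).
#' @export
pair_window_stats <- function(mat, windows, focal_samples, ref_samples,
                              max_missing_frac = 0.5) {
  foc <- pop_window_stats(mat, windows, focal_samples, max_missing_frac)
  ref <- pop_window_stats(mat, windows, ref_samples, max_missing_frac)
  comp <- wc_components(mat, focal_samples, ref_samples, max_missing_frac)
  widx <- window_index(windows, mat$sites$chrom, mat$sites$pos)
  use <- which(comp$ok & !is.na(widx))
  fst <- rep(NA_real_, nrow(windows))
  nsnp <- integer(nrow(windows))
  if (length(use)) {
    dt <- data.table::data.table(w = widx[use], a = comp$a[use],
                                 b = comp$b[use], c = comp$c[use])
    agg <- dt[, list(num = sum(a), den = sum(a + b + c), n = .N), by = "w"]
    ok <- is.finite(agg$den) & agg$den != 0
    fst[agg$w[ok]] <- agg$num[ok] / agg$den[ok]
    nsnp[agg$w] <- agg$n
  }
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = nsnp, fst = fst,
             rod = rod(foc$pi, ref$pi),
             delta_d = delta_tajima(foc$tajima_d, ref$tajima_d),
             pi_focal = foc$pi, pi_ref = ref$pi,
             d_focal = foc$tajima_d, d_ref = ref$tajima_d,
             stringsAsFactors = FALSE)
}

#' Genome-wide group summary
#'
#' Whole-matrix (single "window" per chromosome set) summaries used by the
#' pipeline report: per-bp pi, mean He/Ho over variant sites and multi-locus
#' F_IS for one group of samples.
#'
#' @inheritParams pop_window_stats
#' @param total_bp total genome length in bp used as the pi denominator;
#'   defaults to the sum of observed contig spans.
#' @return one-row data.frame with `pi`, `he`, `ho`, `fis`, `n_snps`.
#' @export
group_summary <- function(mat, samples, total_bp = NULL,
                          max_missing_frac = 0.5) {
  st <- group_site_stats(mat, samples, max_missing_frac)
  if (is.null(total_bp)) {
    cl <- attr(mat, "contig_lengths")
    total_bp <- if (!is.null(cl) && length(cl)) sum(as.numeric(cl)) else
      sum(as.numeric(tapply(mat$sites$pos, mat$sites$chrom, max)))
  }
  sel <- st$keep & st$seg
  he <- if (any(sel)) mean(st$he_site[sel]) else NA_real_
  ho <- if (any(sel)) mean(st$ho_site[sel]) else NA_real_
  data.frame(pi = sum(st$pi_site[sel]) / total_bp,
             he = he, ho = ho,
             fis = inbreeding_fis(he, ho),
             n_snps = sum(sel))
}
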