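#' Genotype r-squared between two sites
#'
#' Squared Pearson correlation of unphased genotype dosages (0/1/2), the
#' composite (Rogers-Huff style) LD estimate. Computed over pairwise-complete
#' entries; at least 3 complete pairs are required, and a site that is
#' constant over the complete pairs yields `NA`.
#'
#' @param g1,g2 equal-length genotype vectors coded 0/1/2 with `NA` missing.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @examples
#' genotype_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)) # 1: perfect negative correlation
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Linkage disequilibrium decay profile
#'
#' Mean genotype r-squared of intra-chromosome site pairs, binned by physical
#' separation. When the number of eligible pairs exceeds `max_pairs`, a
#' seeded uniform subsample is scored instead (deterministic given `seed`).
#'
#' @param mat a [genotype_matrix()].
#' @param samples sample ids of the group.
#' @param max_dist maximum pair separation in bp.
#' @param bin_width distance bin width in bp.
#' @param max_pairs cap on scored pairs (default 200000).
#' @param seed integer seed for the subsample.
#' @param min_maf optional minor-allele-frequency floor for sites entering
#'   the profile. Default 0 (all pairs, as defined); the pipeline instead
#'   applies its variant-level MAF filter upstream.
#' @return object of class `ld_profile`: data.frame of bins (`dist_lo`,
#'   `dist_hi`, `mid`, `mean_r2`, `n_pairs`) with the half-maximum decay
#'   distance attached (see [half_decay_distance()]).
#' @export
ld_decay_profile <- function(mat, samples, max_dist = 50000L,
                             bin_width = 2000L, max_pairs = 200000L,
                             seed = 1L, min_maf = 0) {
  stopifnot(max_dist > 0, bin_width > 0)
  idx <- match(samples, mat$sample_ids)
  if (anyNA(idx)) stop("unknown sample(s) in group")
  G <- mat$geno[idx, , drop = FALSE]
  n_nonmiss <- colSums(!is.na(G))
  p <- ifelse(n_nonmiss > 0, colSums(G, na.rm = TRUE) / (2 * n_nonmiss), NA)
  usable <- which(n_nonmiss >= 3 & !is.na(p) & pmin(p, 1 - p) >= min_maf)

  # enumerate intra-chromosome pairs within max_dist (indices into usable)
  ii <- integer(0); jj <- integer(0)
  for (cn in unique(mat$sites$chrom)) {
    s <- usable[mat$sites$chrom[usable] == cn]
    if (length(s) < 2) next
    posn <- mat$sites$pos[s]
    hi <- findInterval(posn + max_dist, posn)
    n_partners <- hi - seq_along(s)
    from <- rep.int(seq_along(s), n_partners)
    to <- sequence(n_partners, from = seq_along(s) + 1L)
    ii <- c(ii, s[from]); jj <- c(jj, s[to])
  }
  edges <- seq(0L, as.integer(ceiling(max_dist / bin_width)) * bin_width,
               by = bin_width)
  bins <- data.frame(dist_lo = edges[-length(edges)],
                     dist_hi = edges[-1])
  bins$mid <- (bins$dist_lo + bins$dist_hi) / 2
  bins$mean_r2 <- NA_real_
  bins$n_pairs <- 0L

  if (length(ii)) {
    if (length(ii) > max_pairs) {
      old <- .Random.seed_save()
      set.seed(seed)
      pick <- sample.int(length(ii), max_pairs)
      .Random.seed_restore(old)
      ii <- ii[pick]; jj <- jj[pick]
    }
    dist <- mat$sites$pos[jj] - mat$sites$pos[ii]
    bi <- pmin(findInterval(dist, edges, left.open = TRUE) + 0L,
               nrow(bins))
    bi[dist == 0] <- 1L
    r2 <- pair_r2(G, ii, jj)
    ok <- !is.na(r2)
    if (any(ok)) {
      sums <- rowsum(r2[ok], bi[ok])
      cnts <- rowsum(rep(1L, sum(ok)), bi[ok])
      at <- as.integer(rownames(sums))
      bins$mean_r2[at] <- sums[, 1] / cnts[, 1]
      bins$n_pairs[at] <- cnts[, 1]
    }
  }
  out <- structure(bins, class = c("ld_profile", "data.frame"))
  attr(out, "half_decay") <- half_decay_distance(out)
  out
}

# vectorised r^2 for index pairs (ii, jj) into columns of G; falls back to a
# per-pair loop only when the involved columns contain missing genotypes
pair_r2 <- function(G, ii, jj) {
  if (!anyNA(G[, unique(c(ii, jj)), drop = FALSE])) {
    n <- nrow(G)
    cs <- colSums(G)
    css <- colSums(G^2)
    sdv <- sqrt(css - cs^2 / n)  # proportional to sd
    cross <- colSums(G[, ii, drop = FALSE] * G[, jj, drop = FALSE])
    num <- cross - cs[ii] * cs[jj] / n
    den <- sdv[ii] * sdv[jj]
    r2 <- (num / den)^2
    r2[den == 0] <- NA_real_
    r2
  } else {
    vapply(seq_along(ii), function(k) genotype_r2(G[, ii[k]], G[, jj[k]]),
           numeric(1))
  }
}

#' Half-maximum LD decay distance
#'
#' The maximum is the mean r-squared of the first populated bin; the function
#' returns the distance (linear interpolation between bin midpoints) at the
#' first downward crossing of half that maximum, or `NA` when the profile
#' never falls below it within the profiled range.
#'
#' @param profile an `ld_profile` from [ld_decay_profile()], or any
#'   data.frame with `mid`, `mean_r2`, `n_pairs`.
#' @param min_pairs bins with fewer scored pairs than this are treated as
#'   unpopulated (default 1: any scored pair counts; raise on sparse data
#'   where near-empty bins make the curve unreliable).
#' @return distance in bp, or `NA`.
#' @export
half_decay_distance <- function(profile, min_pairs = 1L) {
  pop <- which(profile$n_pairs >= min_pairs & !is.na(profile$mean_r2))
  if (length(pop) < 2) return(NA_real_)
  mid <- profile$mid[pop]
  r2 <- profile$mean_r2[pop]
  target <- r2[1] / 2
  below <- which(r2 < target)
  below <- below[below > 1]
  if (!length(below)) return(NA_real_)
  k <- below[1]
  mid[k - 1] + (r2[k - 1] - target) / (r2[k - 1] - r2[k]) *
    (mid[k] - mid[k - 1])
}

#' @export
print.ld_profile <- function(x, ...) {
  hd <- attr(x, "half_decay")
  cat(sprintf("LD decay profile: %d bins, %d scored pairs\n",
              nrow(x), sum(x$n_pairs)))
  cat(sprintf("  half-maximum decay distance: %s\n",
              if (is.na(hd)) "not reached" else sprintf("%.0f bp", hd)))
  invisible(x)
}

# save/restore the global RNG stream so seeded subsampling does not disturb
# callers' reproducibility
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
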