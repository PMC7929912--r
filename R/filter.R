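#' Filter variants
#'
#' Applies the study-style site filters in a fixed order with
#' first-failing-rule attribution: optional minimum QUAL, SNP-only,
#' biallelic-only, per-site call rate, then minor allele frequency. MAF is
#' computed from non-missing alleles only. Defaults for `maf_min` and
#' `max_missing` are deliberate package choices (the filters used in published analyses of
#' this system are unpublished) and should be surfaced in run configuration, not assumed.
#'
#' @param mat a [genotype_matrix()].
#' @param snps_only drop records whose REF or any ALT allele is not a single
#'   base (indels).
#' @param biallelic_only drop records with more than one ALT allele.
#' @param maf_min minimum minor allele frequency; sites with `maf < maf_min`
#'   are removed (a site exactly at the threshold is kept).
#' @param max_missing maximum fraction of missing genotypes per site.
#' @param min_qual optional minimum QUAL; `NULL` (default) disables the rule.
#'   Sites with missing QUAL are kept.
#' @return list with elements `matrix` (filtered [genotype_matrix()]) and
#'   `report` (class `filter_report`): counts of input records, removals per
#'   rule, and retained records; `input = retained + sum(removed)`.
#' @export
filter_variants <- function(mat, snps_only = TRUE, biallelic_only = TRUE,
                            maf_min = 0.05, max_missing = 0.2,
                            min_qual = NULL) {
  stopifnot(inherits(mat, "genotype_matrix"))
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1)
  m <- nrow(mat$sites)
  removed <- c(low_qual = 0L, non_snp = 0L, multi_allelic = 0L,
               call_rate = 0L, maf = 0L)
  if (m == 0) {
    report <- structure(list(input = 0L, removed = removed, retained = 0L),
                        class = "filter_report")
    return(list(matrix = mat, report = report))
  }
  alive <- rep(TRUE, m)
  fail <- function(rule, idx) {
    idx <- idx & alive
    removed[[rule]] <<- removed[[rule]] + sum(idx)
    alive[idx] <<- FALSE
  }
  if (!is.null(min_qual) && "qual" %in% names(mat$sites)) {
    q <- mat$sites$qual
    fail("low_qual", !is.na(q) & q < min_qual)
  }
  alts <- strsplit(mat$sites$alt, ",", fixed = TRUE)
  if (snps_only) {
    is_snp <- nchar(mat$sites$ref) == 1 &
      vapply(alts, function(a) all(nchar(a) == 1), logical(1))
    fail("non_snp", !is_snp)
  }
  if (biallelic_only) fail("multi_allelic", lengths(alts) > 1)
  n_missing <- colSums(is.na(mat$geno))
  n_samp <- nrow(mat$geno)
  fail("call_rate", n_missing / n_samp > max_missing)
  if (maf_min > 0) {
    nal <- 2L * (n_samp - n_missing)
    j <- colSums(mat$geno, na.rm = TRUE)
    p <- ifelse(nal > 0, j / nal, NA_real_)
    maf <- pmin(p, 1 - p)
    fail("maf", is.na(maf) | maf < maf_min)
  }
  report <- structure(list(input = m, removed = removed,
                           retained = sum(alive)),
                      class = "filter_report")
  list(matrix = subset_matrix(mat, sites = alive), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("variant filter: %d in, %d retained\n", x$input, x$retained))
  for (nm in names(x$removed))
    if (x$removed[[nm]] > 0)
      cat(sprintf("  removed %-13s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  invisible(x)
}

#' Tile contigs with non-overlapping windows
#'
#' Windows are 0-based half-open intervals `[k*size, (k+1)*size)`, the last
#' window of each contig truncated at the contig length, so that every base
#' is covered exactly once.
#'
#' @param contig_lengths named integer vector (`chrom -> length in bp`).
#' @param size window size in bp (> 0).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @examples
#' make_windows(c(chr1 = 120000L), 50000L)
#' @export
make_windows <- function(contig_lengths, size) {
  if (!is.numeric(size) || length(size) != 1 || size <= 0)
    stop("window size must be a single positive number")
  size <- as.integer(size)
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("contig_lengths must be named")
  out <- lapply(names(contig_lengths), function(cn) {
    len <- as.integer(contig_lengths[[cn]])
    if (len <= 0) stop("non-positive contig length for ", cn)
    starts <- seq.int(0L, len - 1L, by = size)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# map 1-based site positions to row indices of a window tiling (NA if the
# site's chromosome is absent from the tiling)
window_index <- function(windows, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (cn in unique(chrom)) {
    w <- which(windows$chrom == cn)
    if (!length(w)) next
    sel <- chrom == cn
    k <- findInterval(pos[sel] - 1L, windows$start[w])
    k[k < 1 | (pos[sel] - 1L) >= windows$end[w][pmax(k, 1L)]] <- NA_integer_
    idx[sel] <- w[k]
  }
  idx
}
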