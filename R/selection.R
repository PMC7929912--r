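#' Fractional-rank empirical P values
#'
#' Distribution-free one-sided P values from the genome-wide empirical
#' distribution of a per-window statistic: for the upper tail,
#' `p = rank_descending / (n + 1)` with average ranks for ties, so all
#' values lie strictly inside (0, 1). Missing statistics propagate as `NA`.
#'
#' @param values numeric vector of per-window statistic values.
#' @param tail `"upper"` (large values are extreme, e.g. F_ST, ROD) or
#'   `"lower"` (small values are extreme, e.g. delta Tajima's D).
#' @return vector of P values, `NA` where the input was `NA`.
#' @examples
#' empirical_pvalues(c(5, 1, 3), "upper") # 0.25 0.75 0.50
#' @export
empirical_pvalues <- function(values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) return(out)
  x <- if (tail == "upper") -values[ok] else values[ok]
  out[ok] <- rank(x, ties.method = "average") / (n + 1)
  out
}

#' Rank correlation matrix of scan statistics
#'
#' Spearman correlation across windows, pairwise-complete, used to derive the
#' decorrelation weights of the composite score. A statistic that is constant
#' across windows gets zero off-diagonal correlation (with a warning).
#'
#' @param stat_table data.frame or matrix, one column per statistic, one row
#'   per window.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
stat_correlation <- function(stat_table) {
  m <- as.matrix(stat_table)
  if (sum(stats::complete.cases(m)) < 10)
    stop("need >= 10 windows with all statistics defined")
  r <- suppressWarnings(cor(m, method = "spearman",
                            use = "pairwise.complete.obs"))
  if (anyNA(r)) {
    warning("constant statistic: off-diagonal correlations set to 0")
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

#' DCMS composite scores
#'
#' Decorrelated composite of multiple signals: each statistic's P value is
#' transformed to a log10 odds of non-extremeness, `log10((1 - p)/p)`, and
#' summed with weight `1 / sum_k |r_ik|` (the inverse total absolute
#' correlation of statistic i with all statistics, itself included). A window
#' with any missing P value gets a missing score. Duplicating a statistic
#' leaves scores unchanged: the duplicate pair's weights halve.
#'
#' @param p_table matrix/data.frame of per-window P values (windows x
#'   statistics), all strictly inside (0, 1) where defined.
#' @param r correlation matrix from [stat_correlation()] (same statistic
#'   order).
#' @return numeric vector of per-window scores.
#' @export
dcms_scores <- function(p_table, r) {
  p <- as.matrix(p_table)
  r <- as.matrix(r)
  if (ncol(p) != nrow(r) || nrow(r) != ncol(r))
    stop("p_table and correlation matrix dimensions disagree")
  bad <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(bad))
    stop("P values must lie strictly inside (0, 1); use fractional ranks")
  w <- 1 / rowSums(abs(r))
  as.vector(log10((1 - p) / p) %*% w)
}

#' Calibrated DCMS P values
#'
#' Fits a robust Gaussian null to the scores (location = median, scale =
#' 1.4826 x MAD) and returns each score's upper-tail probability. When the
#' MAD is zero the standard deviation is used instead, with a warning.
#'
#' @param scores numeric vector of DCMS scores (`NA` allowed, propagated).
#' @return vector of calibrated P values.
#' @export
dcms_pvalues <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 10) stop("need >= 10 defined scores for calibration")
  loc <- median(scores[ok])
  sc <- mad(scores[ok]) # constant = 1.4826 by default
  if (sc == 0) {
    warning("MAD of scores is zero; falling back to standard deviation")
    sc <- sd(scores[ok])
  }
  out <- rep(NA_real_, length(scores))
  out[ok] <- pnorm(scores[ok], mean = loc, sd = sc, lower.tail = FALSE)
  out
}

#' Significant windows
#'
#' Windows with calibrated DCMS P value strictly below the threshold, sorted
#' by P value.
#'
#' @param results data.frame containing at least `chrom`, `start`, `end`,
#'   `p_dcms` (e.g. from [dcms_scan()]).
#' @param threshold significance threshold (default 0.025).
#' @return the significant subset of `results`, ordered by `p_dcms`.
#' @export
significant_windows <- function(results, threshold = 0.025) {
  hit <- !is.na(results$p_dcms) & results$p_dcms < threshold
  out <- results[hit, , drop = FALSE]
  out[order(out$p_dcms), , drop = FALSE]
}

#' Full DCMS selection scan over a pair statistics table
#'
#' Converts the three per-window statistics of a focal-vs-reference
#' comparison into one-sided empirical P values (upper tail for F_ST and ROD,
#' lower tail for delta Tajima's D: a sweep in the focal group elevates
#' differentiation and diversity loss and makes delta-D negative), combines
#' them into DCMS scores with Spearman decorrelation weights, and calibrates
#' the scores against a robust Gaussian null.
#'
#' @param pair_stats data.frame from [pair_window_stats()] (needs `chrom`,
#'   `start`, `end`, `fst`, `rod`, `delta_d`).
#' @param threshold significance threshold on the calibrated P value.
#' @param tails named character vector giving the extreme tail of each
#'   statistic; defaults to `c(fst = "upper", rod = "upper",
#'   delta_d = "lower")`.
#' @return data.frame of class `dcms_result`: window coordinates, the three
#'   component P values (`p_fst`, `p_rod`, `p_deltad`), `dcms`, `p_dcms` and
#'   `significant`; the correlation matrix is attached as attribute
#'   `correlation`.
#' @export
dcms_scan <- function(pair_stats, threshold = 0.025,
                      tails = c(fst = "upper", rod = "upper",
                                delta_d = "lower")) {
  stats_cols <- names(tails)
  if (!all(stats_cols %in% names(pair_stats)))
    stop("pair_stats lacks columns: ",
         paste(setdiff(stats_cols, names(pair_stats)), collapse = ", "))
  p <- vapply(stats_cols, function(sc)
    empirical_pvalues(pair_stats[[sc]], tails[[sc]]),
    numeric(nrow(pair_stats)))
  colnames(p) <- paste0("p_", sub("delta_d", "deltad", stats_cols))
  r <- stat_correlation(pair_stats[, stats_cols])
  scores <- dcms_scores(p, r)
  pd <- dcms_pvalues(scores)
  out <- data.frame(pair_stats[, c("chrom", "start", "end")], p,
                    dcms = scores, p_dcms = pd,
                    significant = !is.na(pd) & pd < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "correlation") <- r
  attr(out, "threshold") <- threshold
  class(out) <- c("dcms_result", "data.frame")
  out
}

#' Genes overlapping significant windows
#'
#' A gene overlaps a window when their 0-based half-open intervals intersect
#' by at least one bp. Genes are deduplicated by name across windows. Genes
#' on chromosomes absent from the window set are skipped with a warning.
#' Uses `GenomicRanges::findOverlaps()` when available, with an equivalent
#' base-R interval sweep otherwise.
#'
#' @param windows data.frame of (typically significant) windows: `chrom`,
#'   `start`, `end`.
#' @param genes BED-style data.frame from [read_genes_bed()].
#' @param chromosomes the chromosome namespace used to detect foreign BED
#'   records; defaults to the windows' own chromosomes, but callers holding
#'   a subset of windows (e.g. significant ones only) should pass the full
#'   contig set.
#' @return list of class `gene_overlap_report`: `windows` (the input),
#'   `genes` (overlapping gene records, deduplicated), `n_windows`,
#'   `n_genes`.
#' @export
genes_in_windows <- function(windows, genes,
                             chromosomes = unique(windows$chrom)) {
  unknown <- setdiff(unique(genes$chrom), chromosomes)
  if (length(unknown)) {
    warning("genes on chromosomes absent from windows skipped: ",
            paste(unknown, collapse = ", "))
    genes <- genes[!genes$chrom %in% unknown, , drop = FALSE]
  }
  hit <- rep(FALSE, nrow(genes))
  if (nrow(windows) && nrow(genes)) {
    if (requireNamespace("GenomicRanges", quietly = TRUE) &&
        requireNamespace("IRanges", quietly = TRUE)) {
      gw <- GenomicRanges::GRanges(windows$chrom,
                                   IRanges::IRanges(windows$start + 1L,
                                                    windows$end))
      gg <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start + 1L,
                                                    genes$end))
      hit <- seq_len(nrow(genes)) %in%
        S4Vectors::subjectHits(GenomicRanges::findOverlaps(gw, gg))
    } else {
      for (k in seq_len(nrow(genes))) {
        w <- windows[windows$chrom == genes$chrom[k], , drop = FALSE]
        hit[k] <- any(w$start < genes$end[k] & genes$start[k] < w$end)
      }
    }
  }
  g <- genes[hit, , drop = FALSE]
  g <- g[!duplicated(g$name), , drop = FALSE]
  structure(list(windows = windows, genes = g,
                 n_windows = nrow(windows), n_genes = nrow(g)),
            class = "gene_overlap_report")
}

#' @export
print.gene_overlap_report <- function(x, ...) {
  cat(sprintf("gene overlap: %d windows, %d distinct genes\n",
              x$n_windows, x$n_genes))
  invisible(x)
}
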