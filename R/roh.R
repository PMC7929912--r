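#' Detect runs of homozygosity for one individual
#'
#' Greedy left-to-right scan over an individual's non-missing genotype calls,
#' chromosome by chromosome. A run accumulates consecutive calls while it
#' contains at most `max_het` heterozygous calls and no positional gap
#' between successive called sites exceeds `max_gap_bp`; when a constraint is
#' violated the run is closed (heterozygous calls are trimmed from both run
#' ends) and a new run starts. Closed runs are kept if they span at least
#' `min_length_bp` and contain at least `min_snps` calls. Missing genotypes
#' neither break nor extend a run unless the gap cap is exceeded.
#'
#' @param mat a [genotype_matrix()].
#' @param sample one sample id.
#' @param min_snps minimum number of genotyped calls in a segment.
#' @param min_length_bp minimum segment span (last - first position + 1).
#' @param max_het maximum number of interior heterozygous calls per segment.
#' @param max_gap_bp maximum distance between successive called sites.
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`
#'   (1-based positions of the first and last call), `n_snps`,
#'   `n_het_allowed_used`.
#' @export
detect_roh <- function(mat, sample, min_snps = 50L, min_length_bp = 100000L,
                       max_het = 1L, max_gap_bp = 1000000L) {
  stopifnot(inherits(mat, "genotype_matrix"))
  ridx <- match(sample, mat$sample_ids)
  if (is.na(ridx)) stop("unknown sample: ", sample)
  g <- mat$geno[ridx, ]
  segs <- list()
  for (cn in unique(mat$sites$chrom)) {
    on_chr <- which(mat$sites$chrom == cn & !is.na(g))
    if (!length(on_chr)) next
    posn <- mat$sites$pos[on_chr]
    het <- g[on_chr] == 1L
    m <- length(on_chr)

    close_run <- function(lo, hi) {
      # trim heterozygous calls from both ends
      while (lo <= hi && het[lo]) lo <- lo + 1L
      while (hi >= lo && het[hi]) hi <- hi - 1L
      if (lo > hi) return(NULL)
      n <- hi - lo + 1L
      span <- posn[hi] - posn[lo] + 1L
      if (n < min_snps || span < min_length_bp) return(NULL)
      data.frame(sample = sample, chrom = cn,
                 start = posn[lo], end = posn[hi],
                 n_snps = n, n_het_allowed_used = sum(het[lo:hi]),
                 stringsAsFactors = FALSE)
    }

    lo <- 1L
    n_het <- 0L
    k <- 2L
    if (het[1L]) n_het <- 1L
    while (k <= m) {
      gap_break <- posn[k] - posn[k - 1L] > max_gap_bp
      het_break <- het[k] && (n_het + 1L > max_het)
      if (gap_break || het_break) {
        segs[[length(segs) + 1L]] <- close_run(lo, k - 1L)
        lo <- k
        n_het <- if (het[k]) 1L else 0L
        if (n_het > max_het) { # run cannot start on an over-budget het
          lo <- k + 1L
          n_het <- 0L
        }
      } else if (het[k]) {
        n_het <- n_het + 1L
      }
      k <- k + 1L
    }
    if (lo <= m) segs[[length(segs) + 1L]] <- close_run(lo, m)
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), n_het_allowed_used = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' Detect runs of homozygosity for many individuals
#'
#' @inheritParams detect_roh
#' @param samples sample ids; defaults to all samples in the matrix.
#' @return row-bound segment table (see [detect_roh()]).
#' @export
detect_roh_all <- function(mat, samples = NULL, min_snps = 50L,
                           min_length_bp = 100000L, max_het = 1L,
                           max_gap_bp = 1000000L) {
  if (is.null(samples)) samples <- mat$sample_ids
  do.call(rbind, lapply(samples, function(s)
    detect_roh(mat, s, min_snps, min_length_bp, max_het, max_gap_bp)))
}

#' Summarise ROH per sample
#'
#' @param segments segment table from [detect_roh()]/[detect_roh_all()].
#' @param samples sample ids to report (samples without segments get
#'   `total_length = 0`, `mean_length = NA`, `n_segments = 0`).
#' @return data.frame: `sample`, `total_length`, `mean_length`, `n_segments`.
#' @export
roh_summary <- function(segments, samples) {
  out <- data.frame(sample = samples, total_length = 0,
                    mean_length = NA_real_, n_segments = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(segments)) {
    len <- as.numeric(segments$end - segments$start + 1L)
    tot <- rowsum(len, segments$sample)
    cnt <- rowsum(rep(1L, nrow(segments)), segments$sample)
    at <- match(rownames(tot), out$sample)
    ok <- !is.na(at)
    out$total_length[at[ok]] <- tot[ok, 1]
    out$n_segments[at[ok]] <- cnt[ok, 1]
    out$mean_length[at[ok]] <- tot[ok, 1] / cnt[ok, 1]
  }
  out
}
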