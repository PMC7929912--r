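#' Diploid genotype matrix
#'
#' The central container of the package: an ordered set of biallelic (or
#' to-be-filtered multi-allelic/indel) variant sites together with diploid
#' genotype codes for a set of samples. Codes are counts of the alternate
#' allele: `0` hom-ref, `1` het, `2` hom-alt, `NA` missing. Sites are kept
#' sorted by (chromosome, position); positions are 1-based as in VCF.
#'
#' @param geno integer matrix, samples in rows, sites in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom` (character), `pos` (integer,
#'   1-based), `ref`, `alt` (character allele strings; multi-allelic records
#'   carry comma-separated `alt`). An optional `qual` column (numeric, `NA`
#'   for missing) is preserved for quality filtering.
#' @param sample_ids character vector of unique sample names, one per row of
#'   `geno`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `sites` and `geno` (the matrix gains sample row names).
#' @examples
#' gm <- genotype_matrix(
#'   geno = matrix(c(0L, 1L, 2L, NA), nrow = 2),
#'   sites = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                      ref = "A", alt = "T"),
#'   sample_ids = c("s1", "s2")
#' )
#' gm
#' @export
genotype_matrix <- function(geno, sites, sample_ids) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(is.character(sample_ids) || length(sample_ids) == 0)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in genotype matrix")
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(sites)))
    stop("sites must have columns chrom, pos, ref, alt")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (nrow(geno) != length(sample_ids))
    stop("geno must have one row per sample")
  if (ncol(geno) != nrow(sites))
    stop("geno must have one column per site")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  # positions strictly increasing within each chromosome
  if (nrow(sites) > 1) {
    same <- sites$chrom[-1] == sites$chrom[-nrow(sites)]
    nondecr <- diff(sites$pos) > 0
    if (any(same & !nondecr))
      stop("site positions must be strictly increasing within chromosomes")
  }
  rownames(geno) <- sample_ids
  rownames(sites) <- NULL
  structure(list(sample_ids = sample_ids, sites = sites, geno = geno),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$sites),
              length(unique(x$sites$chrom))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype fraction: %.4f\n",
              if (length(x$geno)) miss else 0))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param samples character vector of sample ids (or integer indices) to keep;
#'   `NULL` keeps all.
#' @param sites logical or integer index over sites; `NULL` keeps all.
#' @return a `genotype_matrix` with the requested rows/columns.
#' @export
subset_matrix <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ridx <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) {
      miss <- setdiff(samples, x$sample_ids)
      if (length(miss))
        stop("unknown sample(s): ", paste(miss, collapse = ", "))
      match(samples, x$sample_ids)
    } else samples
  }
  cidx <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  genotype_matrix(x$geno[ridx, cidx, drop = FALSE],
                  x$sites[cidx, , drop = FALSE],
                  x$sample_ids[ridx])
}

#' Population map
#'
#' Maps each sample to a population label and a demographic category.
#'
#' @param sample,population character vectors of equal length.
#' @param category character vector in `{"natural", "cultivated",
#'   "introduced"}` (recycled if length 1).
#' @return data.frame of class `population_map`.
#' @export
population_map <- function(sample, population, category) {
  category <- rep_len(as.character(category), length(sample))
  ok <- category %in% c("natural", "cultivated", "introduced")
  if (!all(ok))
    stop("category must be one of natural/cultivated/introduced")
  if (anyDuplicated(sample)) stop("duplicate sample ids in population map")
  out <- data.frame(sample = as.character(sample),
                    population = as.character(population),
                    category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("population_map", "data.frame")
  out
}

# every matrix sample must appear exactly once; populations non-empty
check_popmap <- function(popmap, mat) {
  missing <- setdiff(mat$sample_ids, popmap$sample)
  if (length(missing))
    stop("samples missing from population map: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Sample ids of one group
#'
#' Resolves a population name, or a whole category via the prefix
#' `"category:"` (e.g. `"category:natural"`), to its sample ids.
#'
#' @param popmap a [population_map()].
#' @param group population name or `"category:<name>"`.
#' @return character vector of sample ids (errors if the group is empty).
#' @export
pop_samples <- function(popmap, group) {
  hit <- if (startsWith(group, "category:")) {
    popmap$category == sub("^category:", "", group)
  } else popmap$population == group
  s <- popmap$sample[hit]
  if (!length(s)) stop("group not present in population map: ", group)
  s
}
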