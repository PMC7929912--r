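#' Read a VCF file into a genotype matrix
#'
#' Parses diploid GT calls from a VCF 4.x file. Phasing separators (`|` or
#' `/`) are accepted interchangeably; half-missing calls (e.g. `./1`) are
#' treated as fully missing. Multi-allelic records are retained with the
#' genotype coded as the count of non-reference alleles, so that downstream
#' filtering can account for them; they must be removed by
#' [filter_variants()] before analysis.
#'
#' @param path path to an uncompressed VCF file.
#' @return a [genotype_matrix()]; contig lengths found in `##contig` header
#'   lines are attached as attribute `contig_lengths` (named integer vector).
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !startsWith(lines[hdr[length(hdr)]], "#CHROM"))
    stop("missing #CHROM header line in ", path)
  column_line <- lines[hdr[length(hdr)]]
  cols <- strsplit(sub("^#", "", column_line), "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10 || cols[9] != "FORMAT")
    stop("VCF has no FORMAT/GT columns: ", path)
  sample_ids <- cols[-(1:9)]

  contigs <- grep("^##contig=", lines, value = TRUE)
  contig_lengths <- integer(0)
  if (length(contigs)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contigs)
    lens <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1",
                                            contigs)))
    contig_lengths <- setNames(lens, ids)
  }

  body <- lines[-seq_len(hdr[length(hdr)])]
  body <- body[nzchar(body)]
  if (!length(body)) {
    gm <- genotype_matrix(
      matrix(integer(0), nrow = length(sample_ids), ncol = 0),
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 qual = numeric(0), stringsAsFactors = FALSE),
      sample_ids)
    attr(gm, "contig_lengths") <- contig_lengths
    return(gm)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop("malformed VCF record: ", body[which(nf != length(cols))[1]])
  rec <- do.call(rbind, fields)
  chrom <- rec[, 1]
  pos <- as.integer(rec[, 2])
  # sorted input required: strictly increasing positions per chromosome
  if (nrow(rec) > 1) {
    same <- chrom[-1] == chrom[-length(chrom)]
    if (any(same & diff(pos) <= 0))
      stop("unsorted VCF record: ",
           body[which(same & diff(pos) <= 0)[1] + 1L])
  }
  fmt1 <- vapply(strsplit(rec[, 9], ":", fixed = TRUE), `[`, "", 1L)
  if (any(fmt1 != "GT"))
    stop("GT must be the first FORMAT field: ", body[which(fmt1 != "GT")[1]])
  qual <- suppressWarnings(as.numeric(rec[, 6]))

  gt <- rec[, -(1:9), drop = FALSE]
  # strip any trailing FORMAT subfields, normalise separator
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  u <- unique(as.vector(gt))
  for (val in u) {
    alleles <- strsplit(val, "/", fixed = TRUE)[[1]]
    if (length(alleles) != 2) {
      bad <- which(gt == val, arr.ind = TRUE)[1, 1]
      stop("non-diploid genotype '", val, "' in record: ", body[bad])
    }
    code <- if (any(alleles == ".")) NA_integer_ else {
      ai <- suppressWarnings(as.integer(alleles))
      if (any(is.na(ai))) {
        bad <- which(gt == val, arr.ind = TRUE)[1, 1]
        stop("unparseable genotype '", val, "' in record: ", body[bad])
      }
      sum(ai > 0L)
    }
    codes[gt == val] <- code
  }
  gm <- genotype_matrix(t(codes),
                        data.frame(chrom = chrom, pos = pos,
                                   ref = rec[, 4], alt = rec[, 5],
                                   qual = qual, stringsAsFactors = FALSE),
                        sample_ids)
  attr(gm, "contig_lengths") <- contig_lengths
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits unphased `/`-separated genotypes and `##contig` header lines, so that
#' [read_vcf()] round-trips the matrix exactly.
#'
#' @param mat a [genotype_matrix()].
#' @param path output path.
#' @param contig_lengths named integer vector of contig lengths; defaults to
#'   the matrix's `contig_lengths` attribute, or the maximum observed position
#'   per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(mat, path, contig_lengths = NULL) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (is.null(contig_lengths)) contig_lengths <- attr(mat, "contig_lengths")
  if (is.null(contig_lengths) || !length(contig_lengths)) {
    if (nrow(mat$sites)) {
      contig_lengths <- tapply(mat$sites$pos, mat$sites$chrom, max)
      contig_lengths <- setNames(as.integer(contig_lengths),
                                 names(contig_lengths))
      # preserve first-appearance chromosome order
      contig_lengths <- contig_lengths[unique(mat$sites$chrom)]
    } else contig_lengths <- integer(0)
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=kelpscan-%s",
                   as.character(utils::packageVersion("kelpscan"))),
           sprintf("##contig=<ID=%s,length=%d>",
                   names(contig_lengths), as.integer(contig_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", mat$sample_ids), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(mat$sites)) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[mat$geno + 1L],
                     nrow = nrow(mat$geno))
    gt_str[is.na(mat$geno)] <- "./."
    qual <- if ("qual" %in% names(mat$sites)) {
      ifelse(is.na(mat$sites$qual), ".",
             format(mat$sites$qual, trim = TRUE, scientific = FALSE))
    } else "."
    body <- paste(mat$sites$chrom, mat$sites$pos, ".", mat$sites$ref,
                  mat$sites$alt, qual, "PASS", ".", "GT",
                  sep = "\t")
    gt_cols <- apply(gt_str, 2, paste, collapse = "\t")
    writeLines(paste(body, gt_cols, sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write a sample-to-population map
#'
#' TSV with three columns: `sample`, `population`, `category`
#' (natural/cultivated/introduced). A header line is accepted but optional.
#'
#' @param path TSV path.
#' @return a [population_map()].
#' @export
read_popmap <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t",
                          col.names = c("sample", "population", "category"))
  population_map(dt$sample, dt$population, dt$category)
}

#' @rdname read_popmap
#' @param popmap a [population_map()].
#' @export
write_popmap <- function(popmap, path) {
  data.table::fwrite(as.data.frame(popmap), path, sep = "\t")
  invisible(path)
}

#' Read / write contig lengths
#'
#' Two-column TSV `chrom<TAB>length` (no header).
#' @param path TSV path.
#' @return named integer vector of contig lengths.
#' @export
read_contig_lengths <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  setNames(as.integer(dt$length), as.character(dt$chrom))
}

#' @rdname read_contig_lengths
#' @param contig_lengths named integer vector.
#' @export
write_contig_lengths <- function(contig_lengths, path) {
  data.table::fwrite(data.table::data.table(chrom = names(contig_lengths),
                                            length = as.integer(contig_lengths)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write gene coordinates (BED3+name)
#'
#' Standard BED semantics: 0-based half-open intervals, no header line.
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_genes_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop("BED needs at least 3 columns: ", path)
  if (ncol(dt) == 3) dt[[4]] <- paste0("feature_", seq_len(nrow(dt)))
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]),
                    name = as.character(dt[[4]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$end <= out$start))
    stop("invalid BED intervals in ", path)
  out
}

#' @rdname read_genes_bed
#' @param genes data.frame with `chrom`, `start`, `end`, `name`.
#' @export
write_genes_bed <- function(genes, path) {
  data.table::fwrite(genes[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}
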