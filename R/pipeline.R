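#' Assemble and validate a run configuration
#'
#' A run consumes either an existing VCF (plus population map and optional
#' gene/contig files) or a simulation configuration -- exactly one of the
#' two. All module parameters are surfaced here; outputs are plain TSV with
#' a single header line and `NA` as the missing marker.
#'
#' @param vcf,popmap,genes_bed,contig_lengths input file paths (VCF mode).
#' @param sim a [simulation_config()] (simulation mode).
#' @param out_dir output directory (created if needed).
#' @param pairs list of `c(focal, reference)` population (or
#'   `"category:<name>"`) pairs to scan.
#' @param window_size scan window size in bp (the study design uses 50-kb
#'   windows at genome scale; desk-scale simulations use 2 kb).
#' @param summary_window_size window size for the per-population diversity
#'   summary table.
#' @param maf_min,max_missing,min_qual variant filter settings
#'   (see [filter_variants()]).
#' @param ld_max_dist,ld_bin_width,ld_max_pairs LD profile settings.
#' @param roh_min_snps,roh_min_length,roh_max_het,roh_max_gap ROH scan
#'   settings.
#' @param dcms_threshold significance threshold on the calibrated DCMS P
#'   value.
#' @param seed integer seed governing all stochastic stages.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, genes_bed = NULL,
                       contig_lengths = NULL, sim = NULL,
                       out_dir = tempfile("kelpscan_run_"),
                       pairs = NULL,
                       window_size = 50000L,
                       summary_window_size = 10000L,
                       maf_min = 0.05, max_missing = 0.2, min_qual = NULL,
                       ld_max_dist = 50000L, ld_bin_width = 2000L,
                       ld_max_pairs = 200000L,
                       roh_min_snps = 50L, roh_min_length = 100000L,
                       roh_max_het = 1L, roh_max_gap = 1000000L,
                       dcms_threshold = 0.025,
                       seed = 1L) {
  if (is.null(vcf) == is.null(sim))
    stop("exactly one of vcf or sim must be supplied")
  if (!is.null(vcf) && is.null(popmap))
    stop("VCF mode needs a population map")
  if (window_size <= 0 || summary_window_size <= 0)
    stop("window sizes must be positive")
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  nrow(df)
}

#' Run the full pipeline
#'
#' simulate/read -> filter -> windowed statistics -> LD -> ROH -> DCMS scan,
#' with all tables written under `cfg$out_dir`. While a run is in progress
#' tables carry a `.partial` suffix; they are renamed on success, so an
#' aborted run leaves only `.partial` files behind. A JSON manifest records
#' the configuration echo, input checksums, per-stage row counts and wall
#' times. Given the same configuration and seed the output tables are
#' byte-identical across runs.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(tool = "kelpscan",
                   version = as.character(utils::packageVersion("kelpscan")),
                   mode = if (is.null(cfg$vcf)) "simulation" else "vcf",
                   seed = cfg$seed,
                   window_size = cfg$window_size,
                   dcms_threshold = cfg$dcms_threshold,
                   inputs = list(), stages = list(), timings = list())
  partial <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".tsv.partial"))
    n <- write_tsv(df, p)
    partial <<- c(partial, p)
    manifest$stages[[name]] <<- n
    n
  }
  tick <- local({
    last <- t0
    function(stage) {
      now <- proc.time()[["elapsed"]]
      manifest$timings[[stage]] <<- round(now - last, 3)
      last <<- now
    }
  })
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- acquire -------------------------------------------------------------
  dat <- stage("input", {
    if (is.null(cfg$vcf)) {
      sim_cfg <- cfg$sim
      sim_cfg$seed <- cfg$seed
      sim <- simulate_populations(sim_cfg)
      genes <- make_synthetic_genes(attr(sim$matrix, "contig_lengths"))
      list(mat = sim$matrix, popmap = sim$popmap, genes = genes,
           contigs = attr(sim$matrix, "contig_lengths"),
           truth = sim$truth)
    } else {
      for (p in c(cfg$vcf, cfg$popmap, cfg$genes_bed, cfg$contig_lengths))
        manifest$inputs[[basename(p)]] <- unname(tools::md5sum(p))
      mat <- read_vcf(cfg$vcf)
      contigs <- if (!is.null(cfg$contig_lengths))
        read_contig_lengths(cfg$contig_lengths)
      else attr(mat, "contig_lengths")
      if (is.null(contigs) || !length(contigs))
        stop("contig lengths unavailable (no TSV and no VCF header)")
      genes <- if (!is.null(cfg$genes_bed)) read_genes_bed(cfg$genes_bed)
      list(mat = mat, popmap = read_popmap(cfg$popmap), genes = genes,
           contigs = contigs, truth = NULL)
    }
  })
  check_popmap(dat$popmap, dat$mat)
  if (!is.null(dat$truth)) {
    p <- file.path(cfg$out_dir, "truth.tsv.partial")
    write_truth(dat$truth, p)
    partial <- c(partial, p)
  }
  tick("input")

  # ---- filter --------------------------------------------------------------
  filt <- stage("filter",
                filter_variants(dat$mat, maf_min = cfg$maf_min,
                                max_missing = cfg$max_missing,
                                min_qual = cfg$min_qual))
  mat <- filt$matrix
  attr(mat, "contig_lengths") <- dat$contigs
  emit(data.frame(rule = c("input", names(filt$report$removed), "retained"),
                  count = c(filt$report$input, unname(filt$report$removed),
                            filt$report$retained)),
       "filter_report")
  tick("filter")

  # ---- per-population stats, LD, ROH --------------------------------------
  pops <- unique(dat$popmap$population)
  scan_windows <- make_windows(dat$contigs, cfg$window_size)
  summary_windows <- make_windows(dat$contigs, cfg$summary_window_size)

  stats_tbl <- stage("stats", {
    do.call(rbind, lapply(pops, function(p) {
      s <- pop_samples(dat$popmap, p)
      cbind(population = p,
            pop_window_stats(mat, summary_windows, s))
    }))
  })
  emit(stats_tbl, "population_window_stats")
  summaries <- stage("stats", {
    do.call(rbind, lapply(pops, function(p) {
      s <- pop_samples(dat$popmap, p)
      cbind(population = p,
            group_summary(mat, s, total_bp = sum(as.numeric(dat$contigs))))
    }))
  })
  emit(summaries, "population_summaries")
  tick("stats")

  ld_tbl <- stage("ld", {
    do.call(rbind, lapply(pops, function(p) {
      s <- pop_samples(dat$popmap, p)
      prof <- ld_decay_profile(mat, s, max_dist = cfg$ld_max_dist,
                               bin_width = cfg$ld_bin_width,
                               max_pairs = cfg$ld_max_pairs,
                               seed = cfg$seed)
      cbind(population = p, as.data.frame(prof),
            half_decay = attr(prof, "half_decay"))
    }))
  })
  emit(ld_tbl, "ld_profiles")
  tick("ld")

  roh_segments <- stage("roh",
                        detect_roh_all(mat,
                                       min_snps = cfg$roh_min_snps,
                                       min_length_bp = cfg$roh_min_length,
                                       max_het = cfg$roh_max_het,
                                       max_gap_bp = cfg$roh_max_gap))
  emit(roh_segments, "roh_segments")
  emit(roh_summary(roh_segments, mat$sample_ids), "roh_summary")
  tick("roh")

  # ---- pairwise scans ------------------------------------------------------
  pairs <- cfg$pairs
  if (is.null(pairs)) {
    cats <- unique(dat$popmap$category)
    pairs <- if (all(c("cultivated", "natural") %in% cats))
      list(c("category:cultivated", "category:natural"))
    else if (length(pops) >= 2) list(c(pops[1], pops[2]))
    else list()
  }
  scan_out <- stage("scan", {
    compare_groups(mat, dat$popmap, pairs,
                   windows = scan_windows,
                   threshold = cfg$dcms_threshold)
  })
  for (nm in names(scan_out)) {
    emit(scan_out[[nm]]$pair_stats, paste0("pair_stats_", nm))
    emit(as.data.frame(scan_out[[nm]]$dcms), paste0("dcms_", nm))
    emit(as.data.frame(scan_out[[nm]]$significant),
         paste0("significant_windows_", nm))
    if (!is.null(dat$genes)) {
      rep <- genes_in_windows(scan_out[[nm]]$significant, dat$genes,
                              chromosomes = names(dat$contigs))
      emit(rep$genes, paste0("genes_", nm))
      manifest$stages[[paste0("gene_overlap_", nm)]] <-
        c(windows = rep$n_windows, genes = rep$n_genes)
    }
  }
  tick("scan")

  # ---- finalise ------------------------------------------------------------
  for (p in partial) file.rename(p, sub("\\.partial$", "", p))
  manifest$timings$total <- round(proc.time()[["elapsed"]] - t0, 3)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_lines <- c(sprintf("kelpscan %s run (%s mode, seed %d)",
                         manifest$version, manifest$mode, cfg$seed),
                 vapply(names(manifest$stages), function(nm)
                   sprintf("stage %-40s rows=%s", nm,
                           paste(manifest$stages[[nm]], collapse = "/")),
                   character(1)),
                 vapply(names(manifest$timings), function(nm)
                   sprintf("timing %-39s %.3fs", nm,
                           manifest$timings[[nm]]), character(1)))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(manifest)
}

#' Scan one or more focal-vs-reference group pairs
#'
#' For each `c(focal, reference)` pair, computes the per-window F_ST / ROD /
#' delta Tajima's D table and the DCMS scan. Groups may be population names
#' or `"category:<name>"` selectors. Swapping focal and reference negates
#' delta-D and re-orients ROD (`1 - pi_ref/pi_focal`); by the study's
#' convention the reference is the baseline (natural / earlier) group.
#'
#' @param mat a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param pairs list of `c(focal, reference)` character pairs.
#' @param windows window tiling from [make_windows()].
#' @param threshold DCMS significance threshold.
#' @return named list (one element per pair, named `focal_vs_reference`)
#'   with `pair_stats`, `dcms`, `significant`.
#' @export
compare_groups <- function(mat, popmap, pairs, windows, threshold = 0.025) {
  out <- list()
  for (pr in pairs) {
    if (length(pr) != 2) stop("each pair must be c(focal, reference)")
    focal <- pop_samples(popmap, pr[1])
    ref <- pop_samples(popmap, pr[2])
    if (length(focal) < 2)
      stop("group '", pr[1], "' has fewer than 2 samples")
    if (length(ref) < 2)
      stop("group '", pr[2], "' has fewer than 2 samples")
    ps <- pair_window_stats(mat, windows, focal, ref)
    dc <- dcms_scan(ps, threshold = threshold)
    nm <- paste0(sub("^category:", "", pr[1]), "_vs_",
                 sub("^category:", "", pr[2]))
    out[[nm]] <- list(pair_stats = ps, dcms = dc,
                      significant = significant_windows(dc, threshold))
  }
  out
}
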