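#' Simulation configuration
#'
#' Parameters of the forward Wright-Fisher generator. One configuration
#' describes a set of populations derived from a common ancestral population:
#' `natural` populations split from the ancestor and evolve independently
#' with partial selfing; `cultivated` populations are bred by pooling gametes
#' from all natural populations (random union of gametes, no selfing) for a
#' few generations, emulating pool-based farm breeding; `introduced`
#' populations are founded from the first natural population by a small
#' founder sample, optionally refreshed by serial re-introduction pulses.
#' Optional hard sweeps (single-locus additive viability selection, fitness
#' 1, 1+s, 1+2s) run in a designated focal population.
#'
#' Defaults are desk-scale (N = 500, 100-kb chromosomes); paper-scale sizes
#' are reachable by configuration.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (equal for all).
#' @param ancestral_N diploid size of the ancestral and natural populations.
#' @param generations divergence generations for each natural population
#'   after the split.
#' @param burn_in generations of ancestral burn-in after the stationary-SFS
#'   initialisation (use ~2N when short-range LD must reach drift-
#'   recombination balance).
#' @param mu per-site per-generation mutation rate.
#' @param rho per-bp per-generation crossover probability.
#' @param selfing_rate probability that an offspring is produced by
#'   self-fertilisation (applies to ancestral, natural and introduced
#'   phases; pooled cultivation breeding always outcrosses).
#' @param founder_size diploid founder count of an introduced population.
#' @param founder_gens generations spent at `founder_size` after founding.
#' @param intro_N diploid size of an introduced population after expansion.
#' @param intro_gens generations of the post-expansion introduced phase.
#' @param n_reintroduction_pulses serial migrant pulses from the source into
#'   the introduced population, evenly spaced over the expanded phase.
#' @param pulse_fraction fraction of the introduced population replaced by
#'   source individuals at each pulse.
#' @param pool_mixing if `TRUE`, cultivated populations are bred from the
#'   pooled gametes of all natural populations; if `FALSE` they are simply
#'   split from the first natural population (a non-pooled breeding line).
#' @param pool_generations breeding generations of the cultivated pool.
#' @param pool_N diploid size of the cultivated pool population.
#' @param sweep_loci `NULL`, or data.frame with columns `chrom` (1-based
#'   chromosome index), `pos` (bp) and `s` (selection coefficient) of sweeps
#'   to run in `sweep_population`.
#' @param sweep_population population name carrying the sweep(s); defaults
#'   to the first configured population.
#' @param sweep_max_gens cap on generations waiting for fixation.
#' @param sweep_max_tries restart cap when the sweep allele is lost.
#' @param post_sweep_gens neutral generations after fixation before sampling
#'   (lets new rare variants accumulate: the classic post-sweep signature).
#' @param sample_sizes named integer vector: diploid samples drawn per
#'   population; the names define the populations.
#' @param categories named character vector aligned with `sample_sizes`
#'   giving each population's category (`natural`, `cultivated`,
#'   `introduced`); by default inferred from name prefixes.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return validated list of class `simulation_config`.
#' @seealso [simulate_populations()], [config_neutral()],
#'   [config_demography()], [config_sweep()]
#' @export
simulation_config <- function(n_chromosomes = 2L,
                              chrom_length_bp = 100000L,
                              ancestral_N = 500L,
                              generations = 300L,
                              burn_in = 800L,
                              mu = 1e-6,
                              rho = 5e-7,
                              selfing_rate = 0.4,
                              founder_size = 4L,
                              founder_gens = 5L,
                              intro_N = 100L,
                              intro_gens = 60L,
                              n_reintroduction_pulses = 0L,
                              pulse_fraction = 0.25,
                              pool_mixing = TRUE,
                              pool_generations = 5L,
                              pool_N = 200L,
                              sweep_loci = NULL,
                              sweep_population = NULL,
                              sweep_max_gens = 500L,
                              sweep_max_tries = 200L,
                              post_sweep_gens = 150L,
                              sample_sizes = c(natural1 = 8L, natural2 = 8L),
                              categories = NULL,
                              seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              ancestral_N = as.integer(ancestral_N),
              generations = as.integer(generations),
              burn_in = as.integer(burn_in),
              mu = mu, rho = rho, selfing_rate = selfing_rate,
              founder_size = as.integer(founder_size),
              founder_gens = as.integer(founder_gens),
              intro_N = as.integer(intro_N),
              intro_gens = as.integer(intro_gens),
              n_reintroduction_pulses = as.integer(n_reintroduction_pulses),
              pulse_fraction = pulse_fraction,
              pool_mixing = isTRUE(pool_mixing),
              pool_generations = as.integer(pool_generations),
              pool_N = as.integer(pool_N),
              sweep_loci = sweep_loci,
              sweep_population = sweep_population,
              sweep_max_gens = as.integer(sweep_max_gens),
              sweep_max_tries = as.integer(sweep_max_tries),
              post_sweep_gens = as.integer(post_sweep_gens),
              sample_sizes = sample_sizes,
              categories = categories,
              seed = as.integer(seed))

  if (cfg$n_chromosomes < 1 || cfg$chrom_length_bp < 1)
    stop("invalid genome dimensions")
  for (rate in c("mu", "rho", "selfing_rate", "pulse_fraction"))
    if (!is.numeric(cfg[[rate]]) || cfg[[rate]] < 0 || cfg[[rate]] > 1)
      stop(rate, " must lie in [0, 1]")
  if (cfg$ancestral_N < 2) stop("ancestral_N must be >= 2")
  if (cfg$founder_size < 1 || cfg$founder_size > cfg$ancestral_N)
    stop("founder_size must be in [1, ancestral_N]")
  if (is.null(names(cfg$sample_sizes)) ||
      any(!nzchar(names(cfg$sample_sizes))))
    stop("sample_sizes must be a named vector (names = populations)")
  cfg$sample_sizes <- setNames(as.integer(sample_sizes),
                               names(sample_sizes))
  if (any(cfg$sample_sizes < 1)) stop("sample sizes must be >= 1")
  if (is.null(cfg$categories)) {
    nm <- names(cfg$sample_sizes)
    cfg$categories <- setNames(ifelse(
      startsWith(nm, "cultivated"), "cultivated",
      ifelse(startsWith(nm, "introduced"), "introduced", "natural")), nm)
  }
  if (!identical(sort(names(cfg$categories)),
                 sort(names(cfg$sample_sizes))))
    stop("categories must be named like sample_sizes")
  cfg$categories <- cfg$categories[names(cfg$sample_sizes)]
  if (!all(cfg$categories %in% c("natural", "cultivated", "introduced")))
    stop("categories must be natural/cultivated/introduced")
  if (!any(cfg$categories == "natural"))
    stop("at least one natural population is required")
  if (!is.null(cfg$sweep_loci)) {
    sl <- as.data.frame(cfg$sweep_loci)
    if (!all(c("chrom", "pos", "s") %in% names(sl)))
      stop("sweep_loci needs columns chrom, pos, s")
    if (any(sl$chrom < 1 | sl$chrom > cfg$n_chromosomes) ||
        any(sl$pos < 1 | sl$pos > cfg$chrom_length_bp))
      stop("sweep loci outside the genome")
    if (any(sl$s <= 0)) stop("selection coefficients must be positive")
    cfg$sweep_loci <- sl
    if (is.null(cfg$sweep_population))
      cfg$sweep_population <- names(cfg$sample_sizes)[1]
    if (!cfg$sweep_population %in% names(cfg$sample_sizes))
      stop("sweep_population not among configured populations")
  }
  structure(cfg, class = "simulation_config")
}

# ---- internal population state ---------------------------------------------
# pop: list(rows = integer matrix (2N x S, 0/1), chrom, pos (int vectors,
# sorted), fixed_keys (numeric), census = data.frame(generation, N))

key_of <- function(chrom, pos) chrom * 4e9 + pos

# union of active (segregating or fixed-derived) site keys over states
active_keys <- function(states) {
  unique(unlist(lapply(states, function(p)
    c(key_of(p$chrom, p$pos), p$fixed_keys))))
}

# stationary infinite-sites SFS initialisation in linkage equilibrium
equilibrium_init <- function(n_hap, cfg) {
  n_sites_total <- 0L
  chroms <- integer(0); poss <- integer(0); counts <- integer(0)
  i <- seq_len(n_hap - 1)
  sfs_w <- (1 / i) / sum(1 / i)
  a1 <- sum(1 / i)
  for (c in seq_len(cfg$n_chromosomes)) {
    theta_c <- 4 * cfg$ancestral_N * cfg$mu * cfg$chrom_length_bp
    S <- stats::rpois(1, theta_c * a1)
    if (S == 0) next
    pos <- sort(sample.int(cfg$chrom_length_bp, S))
    chroms <- c(chroms, rep.int(c, S))
    poss <- c(poss, pos)
    counts <- c(counts, sample.int(n_hap - 1, S, replace = TRUE,
                                   prob = sfs_w))
    n_sites_total <- n_sites_total + S
  }
  H <- matrix(0L, nrow = n_hap, ncol = n_sites_total)
  for (s in seq_len(n_sites_total))
    H[sample.int(n_hap, counts[s]), s] <- 1L
  list(rows = H, chrom = chroms, pos = poss, fixed_keys = numeric(0),
       census = data.frame(generation = integer(0), N = integer(0)))
}

# advance one population by one engine phase; `forbidden` holds site keys
# active in other populations of the same simulation (the population's own
# fixed-derived keys are always added)
wf_phase <- function(pop, cfg, n_gens, N_out, selfing,
                     sweep = NULL, forbidden = numeric(0)) {
  if (n_gens == 0 && nrow(pop$rows) == 2L * N_out) return(pop)
  sw_chrom <- -1L; sw_pos <- -1L; sw_s <- 0
  sw_intro <- FALSE; stop_fix <- FALSE; stop_loss <- FALSE
  if (!is.null(sweep)) {
    sw_chrom <- sweep$chrom; sw_pos <- sweep$pos; sw_s <- sweep$s
    sw_intro <- isTRUE(sweep$introduce)
    stop_fix <- isTRUE(sweep$stop_on_fix)
    stop_loss <- isTRUE(sweep$stop_on_loss)
  }
  res <- .wf_evolve_cpp(pop$rows, pop$chrom, pop$pos,
                        rep(cfg$chrom_length_bp, cfg$n_chromosomes),
                        n_gens, N_out, cfg$mu, cfg$rho, selfing,
                        sw_chrom, sw_pos, sw_s, sw_intro,
                        stop_fix, stop_loss,
                        unique(c(forbidden, pop$fixed_keys)))
  out <- list(rows = res$H, chrom = res$chrom, pos = res$pos,
              fixed_keys = c(pop$fixed_keys,
                             key_of(res$fixed_chrom, res$fixed_pos)),
              census = rbind(pop$census,
                             data.frame(generation = seq_len(res$gens_run) +
                                          nrow_or0(pop$census),
                                        N = N_out)))
  attr(out, "sweep_status") <- res$sweep_status
  attr(out, "sweep_count") <- res$sweep_count
  attr(out, "gens_run") <- res$gens_run
  out
}

nrow_or0 <- function(df) if (is.null(df)) 0L else nrow(df)

# expand a population's rows onto a superset of site keys (numeric, sorted):
# absent segregating keys become the ancestral allele unless fixed-derived
expand_rows <- function(pop, union_keys) {
  out <- matrix(0L, nrow = nrow(pop$rows), ncol = length(union_keys))
  own <- key_of(pop$chrom, pop$pos)
  at <- match(own, union_keys)
  out[, at[!is.na(at)]] <- pop$rows[, !is.na(at), drop = FALSE]
  fx <- match(intersect(pop$fixed_keys, union_keys), union_keys)
  if (length(fx)) out[, fx] <- 1L
  out
}

# merge populations' haplotypes over the union of their segregating sites
merge_pops <- function(pops) {
  union_keys <- sort(unique(unlist(lapply(pops, function(p)
    key_of(p$chrom, p$pos)))))
  rows <- do.call(rbind, lapply(pops, expand_rows, union_keys = union_keys))
  fixed_all <- Reduce(intersect, lapply(pops, function(p) p$fixed_keys))
  # drop union columns that became monomorphic across the merged set
  cs <- colSums(rows)
  mono_hi <- cs == nrow(rows)
  fixed_all <- sort(unique(c(fixed_all, union_keys[mono_hi])))
  keep <- cs > 0 & !mono_hi
  union_keys <- union_keys[keep]
  list(rows = rows[, keep, drop = FALSE],
       chrom = as.integer(union_keys %/% 4e9),
       pos = as.integer(union_keys %% 4e9),
       fixed_keys = fixed_all,
       census = data.frame(generation = integer(0), N = integer(0)))
}

# label a per-population census table, tolerating zero-row tables
label_census <- function(name, census) {
  if (nrow(census) == 0)
    return(data.frame(population = character(0), generation = integer(0),
                      N = integer(0)))
  cbind(population = name, census)
}

# take a diploid subset of a population
take_individuals <- function(pop, idx) {
  rows <- pop$rows[as.vector(rbind(2L * idx - 1L, 2L * idx)), ,
                   drop = FALSE]
  list(rows = rows, chrom = pop$chrom, pos = pop$pos,
       fixed_keys = pop$fixed_keys, census = pop$census)
}

run_sweep_phase <- function(pop, cfg, locus, forbidden) {
  # if the requested position already carries a variant (here or in another
  # population), shift to the nearest free coordinate
  taken <- c(key_of(pop$chrom, pop$pos), pop$fixed_keys, forbidden)
  pos <- as.integer(locus$pos)
  while (key_of(locus$chrom, pos) %in% taken &&
         pos < cfg$chrom_length_bp) pos <- pos + 1L
  tries <- 0L
  repeat {
    tries <- tries + 1L
    attempt <- wf_phase(pop, cfg, cfg$sweep_max_gens, nrow(pop$rows) / 2L,
                        cfg$selfing_rate,
                        sweep = list(chrom = locus$chrom, pos = pos,
                                     s = locus$s, introduce = TRUE,
                                     stop_on_fix = TRUE,
                                     stop_on_loss = TRUE),
                        forbidden = forbidden)
    status <- attr(attempt, "sweep_status")
    if (status == 2L || status == 1L || tries >= cfg$sweep_max_tries) {
      attr(attempt, "tries") <- tries
      attr(attempt, "fixed") <- status == 2L
      attr(attempt, "realized_pos") <- pos
      return(attempt)
    }
    # allele lost: restart from the pre-sweep state (RNG has advanced)
    attempt <- NULL
  }
}

#' Simulate populations under the configured demography
#'
#' Runs the forward Wright-Fisher engine through the configured phase graph
#' (ancestral burn-in, natural splits, pooled cultivation breeding, founder
#' introductions with optional re-introduction pulses, optional sweeps) and
#' samples diploid individuals from each population.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `matrix` (a [genotype_matrix()] over the union
#'   of sites segregating in any population; sites monomorphic within the
#'   drawn sample are retained and flagged in the attribute
#'   `monomorphic_in_sample`), `popmap` (a [population_map()]) and `truth`
#'   (class `simulation_truth`: expected neutral diversity
#'   `theta = 4 N mu`, realized sweep outcomes, per-population census
#'   sizes per generation).
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)

  pops <- list()
  census <- list()
  nm <- names(cfg$sample_sizes)
  cat_of <- cfg$categories

  # ancestral phase
  anc <- equilibrium_init(2L * cfg$ancestral_N, cfg)
  anc <- wf_phase(anc, cfg, cfg$burn_in, cfg$ancestral_N, cfg$selfing_rate)
  census[["ancestral"]] <- label_census("ancestral", anc$census)

  sweep_truth <- NULL
  naturals <- nm[cat_of == "natural"]
  # forbidden positions for the population currently evolving: sites active
  # in the ancestor or in any already-finalized population
  forb <- function() active_keys(c(list(anc), pops))

  evolve_with_optional_sweep <- function(pop, name, n_gens, N_out, selfing) {
    if (!is.null(cfg$sweep_loci) && identical(cfg$sweep_population, name)) {
      sw <- list()
      for (k in seq_len(nrow(cfg$sweep_loci))) {
        locus <- cfg$sweep_loci[k, ]
        pop <- run_sweep_phase(pop, cfg, locus, forb())
        sw[[k]] <- data.frame(chrom = locus$chrom, pos = locus$pos,
                              realized_pos = attr(pop, "realized_pos"),
                              s = locus$s,
                              fixed = attr(pop, "fixed"),
                              tries = attr(pop, "tries"),
                              gens_to_fix = attr(pop, "gens_run"))
      }
      sweep_truth <<- do.call(rbind, sw)
      pop <- wf_phase(pop, cfg, cfg$post_sweep_gens, N_out, selfing,
                      forbidden = forb())
    } else {
      pop <- wf_phase(pop, cfg, n_gens, N_out, selfing, forbidden = forb())
    }
    pop
  }

  for (name in naturals) {
    pop <- anc # split: copy of ancestral state
    pop$census <- pop$census[0, ]
    pop <- evolve_with_optional_sweep(pop, name, cfg$generations,
                                      cfg$ancestral_N, cfg$selfing_rate)
    pops[[name]] <- pop
    census[[name]] <- label_census(name, pop$census)
  }

  for (name in nm[cat_of == "introduced"]) {
    src <- pops[[naturals[1]]]
    founders <- sort(sample.int(cfg$ancestral_N, cfg$founder_size))
    pop <- take_individuals(src, founders)
    pop$census <- pop$census[0, ]
    pop <- wf_phase(pop, cfg, cfg$founder_gens, cfg$founder_size,
                    cfg$selfing_rate, forbidden = forb())
    if (cfg$n_reintroduction_pulses > 0) {
      chunks <- cfg$n_reintroduction_pulses + 1L
      per <- diff(round(seq(0, cfg$intro_gens, length.out = chunks + 1L)))
      for (ch in seq_len(chunks)) {
        pop <- wf_phase(pop, cfg, per[ch], cfg$intro_N,
                        cfg$selfing_rate, forbidden = forb())
        if (ch < chunks) {
          n_mig <- max(1L, round(cfg$pulse_fraction * cfg$intro_N))
          mig <- take_individuals(src,
                                  sort(sample.int(cfg$ancestral_N, n_mig)))
          keepers <- take_individuals(pop,
                                      sort(sample.int(cfg$intro_N,
                                                      cfg$intro_N - n_mig)))
          cen <- pop$census
          pop <- merge_pops(list(keepers, mig))
          pop$census <- cen
        }
      }
      pop <- evolve_with_optional_sweep(pop, name, 0L, cfg$intro_N,
                                        cfg$selfing_rate)
    } else {
      pop <- evolve_with_optional_sweep(pop, name, cfg$intro_gens,
                                        cfg$intro_N, cfg$selfing_rate)
    }
    pops[[name]] <- pop
    census[[name]] <- label_census(name, pop$census)
  }

  for (name in nm[cat_of == "cultivated"]) {
    pop <- if (cfg$pool_mixing) {
      merge_pops(pops[naturals])
    } else {
      p <- pops[[naturals[1]]]; p$census <- p$census[0, ]; p
    }
    pop$census <- pop$census[0, ]
    selfing <- if (cfg$pool_mixing) 0 else cfg$selfing_rate
    pop <- evolve_with_optional_sweep(pop, name, cfg$pool_generations,
                                      cfg$pool_N, selfing)
    pops[[name]] <- pop
    census[[name]] <- label_census(name, pop$census)
  }

  # ---- sample individuals and emit the union genotype matrix --------------
  union_keys <- sort(unique(unlist(lapply(pops, function(p)
    key_of(p$chrom, p$pos)))))
  # drop keys fixed-derived in every population (global substitutions)
  geno_list <- list()
  sample_ids <- character(0)
  pop_lab <- character(0)
  for (name in nm) {
    pop <- pops[[name]]
    n_avail <- nrow(pop$rows) / 2L
    k <- cfg$sample_sizes[[name]]
    if (k > n_avail)
      stop("population ", name, " has only ", n_avail, " individuals")
    idx <- sort(sample.int(n_avail, k))
    sub <- take_individuals(pop, idx)
    rows <- expand_rows(sub, union_keys)
    g <- rows[seq(1, nrow(rows), by = 2), , drop = FALSE] +
      rows[seq(2, nrow(rows), by = 2), , drop = FALSE]
    geno_list[[name]] <- g
    ids <- sprintf("%s_%02d", name, seq_len(k))
    sample_ids <- c(sample_ids, ids)
    pop_lab <- c(pop_lab, rep(name, k))
  }
  geno <- do.call(rbind, geno_list)
  cs <- colSums(geno)
  mono <- cs == 0L | cs == nrow(geno) * 2L

  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  sites <- data.frame(
    chrom = chrom_names[as.integer(union_keys %/% 4e9)],
    pos = as.integer(union_keys %% 4e9),
    ref = "A", alt = "T", qual = NA_real_, stringsAsFactors = FALSE)
  mat <- genotype_matrix(geno, sites, sample_ids)
  attr(mat, "contig_lengths") <- setNames(
    rep(cfg$chrom_length_bp, cfg$n_chromosomes), chrom_names)
  attr(mat, "monomorphic_in_sample") <- mono

  popmap <- population_map(sample_ids, pop_lab,
                           cfg$categories[pop_lab])
  truth <- structure(list(
    theta = 4 * cfg$ancestral_N * cfg$mu,
    sweeps = if (is.null(sweep_truth))
      data.frame(chrom = integer(0), pos = integer(0),
                 realized_pos = integer(0), s = numeric(0),
                 fixed = logical(0), tries = integer(0),
                 gens_to_fix = integer(0))
    else sweep_truth,
    census = do.call(rbind, census)), class = "simulation_truth")
  list(matrix = mat, popmap = popmap, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation truth: theta = %.4g, %d sweep locus/loci\n",
              x$theta, nrow(x$sweeps)))
  invisible(x)
}

#' Write / read simulation ground truth
#'
#' Single TSV holding the expected neutral diversity, realized sweep
#' outcomes and per-population census sizes; [read_truth()] restores an
#' equal `simulation_truth` record.
#'
#' @param truth a `simulation_truth` from [simulate_populations()].
#' @param path output TSV path.
#' @return `path` invisibly (`write_truth`); a `simulation_truth`
#'   (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  rows <- data.table::data.table(
    record = "theta", population = NA_character_, chrom = NA_integer_,
    pos = NA_integer_, realized_pos = NA_integer_, s = NA_real_,
    fixed = NA, tries = NA_integer_, generation = NA_integer_,
    N = NA_integer_, value = truth$theta)
  if (nrow(truth$sweeps))
    rows <- rbind(rows, data.table::data.table(
      record = "sweep", population = NA_character_,
      chrom = truth$sweeps$chrom, pos = truth$sweeps$pos,
      realized_pos = truth$sweeps$realized_pos,
      s = truth$sweeps$s, fixed = truth$sweeps$fixed,
      tries = truth$sweeps$tries, generation = truth$sweeps$gens_to_fix,
      N = NA_integer_, value = NA_real_))
  if (nrow(truth$census))
    rows <- rbind(rows, data.table::data.table(
      record = "census", population = truth$census$population,
      chrom = NA_integer_, pos = NA_integer_, realized_pos = NA_integer_,
      s = NA_real_, fixed = NA,
      tries = NA_integer_, generation = truth$census$generation,
      N = truth$census$N, value = NA_real_))
  data.table::fwrite(rows, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  th <- dt[dt$record == "theta", ]
  sw <- dt[dt$record == "sweep", ]
  cs <- dt[dt$record == "census", ]
  structure(list(
    theta = th$value[1],
    sweeps = data.frame(chrom = as.integer(sw$chrom),
                        pos = as.integer(sw$pos),
                        realized_pos = as.integer(sw$realized_pos),
                        s = as.numeric(sw$s),
                        fixed = as.logical(sw$fixed),
                        tries = as.integer(sw$tries),
                        gens_to_fix = as.integer(sw$generation)),
    census = data.frame(population = as.character(cs$population),
                        generation = as.integer(cs$generation),
                        N = as.integer(cs$N))),
    class = "simulation_truth")
}

#' Uniformly spaced synthetic gene track
#'
#' Writes plausibility-scale gene features (0-based half-open BED intervals)
#' across the configured genome, for exercising gene-overlap reporting.
#'
#' @param contig_lengths named integer vector.
#' @param gene_length gene span in bp.
#' @param spacing distance between successive gene starts in bp.
#' @return data.frame `chrom`, `start`, `end`, `name` (synthetic labels).
#' @export
make_synthetic_genes <- function(contig_lengths, gene_length = 1000L,
                                 spacing = 3000L) {
  stopifnot(gene_length > 0, spacing >= gene_length)
  out <- lapply(names(contig_lengths), function(cn) {
    len <- as.integer(contig_lengths[[cn]])
    starts <- seq.int(0L, max(0L, len - gene_length), by = spacing)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + gene_length, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$name <- sprintf("synthetic_gene_%04d", seq_len(nrow(out)))
  out
}

# ---- canned scenario configurations ----------------------------------------

#' Canned scenario: neutral two-population split
#'
#' One 100-kb chromosome, N = 500, mu = 1e-6, no selfing; two natural
#' populations split from the ancestor with a short divergence. Used for
#' neutral calibration: expected per-bp diversity is `4 N mu = 2e-3`.
#'
#' @param seed integer seed.
#' @param n_chromosomes number of chromosomes (default 1).
#' @return a [simulation_config()].
#' @export
config_neutral <- function(seed = 1L, n_chromosomes = 1L) {
  simulation_config(
    n_chromosomes = n_chromosomes, chrom_length_bp = 100000L,
    ancestral_N = 500L, burn_in = 200L, generations = 50L,
    mu = 1e-6, rho = 5e-7, selfing_rate = 0,
    sample_sizes = c(natural1 = 8L, natural2 = 8L),
    seed = seed)
}

#' Canned scenario: the three demographic archetypes
#'
#' Two selfing natural populations (the native beds), one pool-bred
#' cultivated population (gametes pooled across the naturals, outcrossing)
#' and one founder-effect introduced population (4 founders, then a
#' sustained small census of 50 for ~30 generations: a recent introduction).
#' Six 50-kb chromosomes give enough independent linkage blocks for stable
#' F_IS and ROH contrasts at 8 samples per population; burn-in is ~1.6N
#' generations so short-range LD approaches drift-recombination balance
#' before the split.
#'
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
config_demography <- function(seed = 1L) {
  simulation_config(
    n_chromosomes = 6L, chrom_length_bp = 50000L,
    ancestral_N = 500L, burn_in = 800L, generations = 300L,
    mu = 1e-6, rho = 5e-7, selfing_rate = 0.4,
    founder_size = 4L, founder_gens = 5L, intro_N = 50L, intro_gens = 30L,
    pool_mixing = TRUE, pool_generations = 5L, pool_N = 200L,
    sample_sizes = c(natural1 = 8L, natural2 = 8L,
                     cultivated1 = 8L, introduced1 = 8L),
    seed = seed)
}

#' Canned scenario: hard sweep in a focal population
#'
#' Two outcrossing natural populations split from the ancestor; the focal
#' one carries a single hard sweep (s = 0.2, additive) from a new mutation
#' on chromosome 1, run to fixation (restarting on loss) and then sampled
#' 150 generations later so the swept region is repopulated by rare
#' variants. Six chromosomes keep five-sixths of the genome as neutral
#' background for the empirical ranks and the robust null of the scan; the
#' locus sits at the centre of a 4-kb scan window.
#'
#' @param seed integer seed.
#' @param s selection coefficient (>= 0.1 gives a hard sweep at this scale).
#' @return a [simulation_config()].
#' @export
config_sweep <- function(seed = 1L, s = 0.2) {
  simulation_config(
    n_chromosomes = 6L, chrom_length_bp = 80000L,
    ancestral_N = 500L, burn_in = 200L, generations = 220L,
    mu = 1e-6, rho = 5e-7, selfing_rate = 0,
    sweep_loci = data.frame(chrom = 1L, pos = 42000L, s = s),
    sweep_population = "focal",
    sweep_max_gens = 500L, sweep_max_tries = 200L, post_sweep_gens = 150L,
    sample_sizes = c(focal = 10L, reference = 10L),
    seed = seed)
}
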