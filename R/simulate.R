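# Wright-Fisher forward simulator: populations of constant diploid size Ne
# diverge from one ancestral haplotype pool by pure drift, with recombining
# phased chromosomes, optional positive selection at one locus in one
# population, planted relatives, per-SNP missingness, and full ground truth.
# Forward-in-time simulation is used (rather than a coalescent) so that
# sweeps, pedigrees and runs of homozygosity arise mechanistically.

#' Simulation configuration
#'
#' Defaults describe the desk-scale world used throughout the test suite:
#' two populations of Ne = 100 diverging for 20 generations on two 50-Mbps
#' chromosomes of 500 SNPs each at 1 cM/Mb, ancestral allele frequencies
#' from Beta(0.5, 0.5) (mimicking array ascertainment toward spread
#' frequencies), 50 diploids sampled per population, no missingness.
#'
#' @param seed RNG seed; the whole dataset is a deterministic function of it.
#' @param n_populations number of diverging populations (2-4 typical).
#' @param ne diploid effective size per population (scalar or vector).
#' @param generations divergence time in generations.
#' @param n_chromosomes,chrom_length_bp,n_snps_per_chrom genome layout.
#' @param recomb_cm_per_mb recombination rate (default 1 cM/Mb).
#' @param ancestral_freq "beta" or "uniform".
#' @param beta_a,beta_b,unif_min,unif_max ancestral frequency distribution
#'   parameters.
#' @param sweep NULL, or a list with elements `population` (index), `chrom`
#'   (index), `pos` (bp; the nearest SNP is used), `s` (selection
#'   coefficient; genotype fitness 1, 1+s, 1+2s), `start_generation`,
#'   optional `initial_freq` (forces the ancestral frequency at the swept
#'   SNP) and `condition_on_fixation` (resimulate with incremented seed
#'   until the allele is fixed in the target population; bounded retries).
#' @param sample_sizes diploids sampled per population (recycled).
#' @param missing_rate i.i.d. genotype missingness in \[0, 1).
#' @param max_retries bound on conditioning retries (default 50).
#' @return validated configuration list.
#' @export
sim_config <- function(seed = 1L, n_populations = 2L, ne = 100L,
                       generations = 20L, n_chromosomes = 2L,
                       chrom_length_bp = 5e7, n_snps_per_chrom = 500L,
                       recomb_cm_per_mb = 1,
                       ancestral_freq = c("beta", "uniform"),
                       beta_a = 0.5, beta_b = 0.5,
                       unif_min = 0.05, unif_max = 0.95,
                       sweep = NULL, sample_sizes = 50L,
                       missing_rate = 0, max_retries = 50L) {
  ancestral_freq <- match.arg(ancestral_freq)
  cfg <- list(seed = as.integer(seed),
              n_populations = as.integer(n_populations),
              ne = rep_len(as.integer(ne), n_populations),
              generations = as.integer(generations),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              recomb_cm_per_mb = recomb_cm_per_mb,
              ancestral_freq = ancestral_freq,
              beta_a = beta_a, beta_b = beta_b,
              unif_min = unif_min, unif_max = unif_max,
              sweep = sweep,
              sample_sizes = rep_len(as.integer(sample_sizes), n_populations),
              missing_rate = missing_rate,
              max_retries = as.integer(max_retries))
  stopifnot(cfg$n_populations >= 1L, all(cfg$ne > 0L), cfg$generations >= 0L,
            cfg$n_chromosomes >= 1L, cfg$n_snps_per_chrom > 0L,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            all(cfg$sample_sizes > 0L), all(cfg$sample_sizes <= cfg$ne))
  if (!is.null(sweep)) {
    stopifnot(sweep$s >= 0, sweep$population >= 1L,
              sweep$population <= cfg$n_populations,
              sweep$chrom >= 1L, sweep$chrom <= cfg$n_chromosomes)
  }
  cfg
}

#' @keywords internal
#' @noRd
gamete_block <- function(H, parents, pos_m, L_m) {
  # one gamete per entry of `parents` from the diploid rows (2p-1, 2p) of H;
  # crossovers are Poisson(L_m) with uniform positions, start phase random
  n_g <- length(parents)
  m <- ncol(H)
  k <- stats::rpois(n_g, L_m)
  start <- sample.int(2L, n_g, replace = TRUE) - 1L
  out <- matrix(0L, n_g, m)
  no_x <- k == 0L
  if (any(no_x))
    out[no_x, ] <- H[2L * parents[no_x] - 1L + start[no_x], , drop = FALSE]
  for (i in which(!no_x)) {
    br <- sort(stats::runif(k[i], 0, L_m))
    cuts <- c(0L, findInterval(br, pos_m), m)   # slice boundaries in SNP index
    ph <- start[i]
    row <- 2L * parents[i] - 1L
    for (sgt in seq_len(length(cuts) - 1L)) {
      if (cuts[sgt + 1L] > cuts[sgt])
        out[i, (cuts[sgt] + 1L):cuts[sgt + 1L]] <- H[row + ph, (cuts[sgt] + 1L):cuts[sgt + 1L]]
      ph <- 1L - ph
    }
  }
  out
}

#' @keywords internal
#' @noRd
evolve_population <- function(haps, pos_m_list, L_m, ne, generations,
                              sweep_site = NULL) {
  # haps: list per chromosome of (2*ne x M) matrices. sweep_site: NULL or
  # list(chrom, index, s, start_generation).
  if (generations == 0L) return(list(haps = haps, lost = FALSE, fix_gen = NA))
  n_chrom <- length(haps)
  fix_gen <- NA_integer_
  for (gen in seq_len(generations)) {
    w <- rep(1, ne)
    if (!is.null(sweep_site) && gen >= sweep_site$start_generation) {
      hc <- haps[[sweep_site$chrom]]
      gsw <- hc[seq(1L, 2L * ne, 2L), sweep_site$index] +
        hc[seq(2L, 2L * ne, 2L), sweep_site$index]
      w <- 1 + sweep_site$s * gsw
      if (sum(gsw) == 0L && sweep_site$s > 0)
        return(list(haps = haps, lost = TRUE))
    }
    mothers <- sample.int(ne, ne, replace = TRUE, prob = w)
    fathers <- sample.int(ne, ne, replace = TRUE, prob = w)
    for (ch in seq_len(n_chrom)) {
      g1 <- gamete_block(haps[[ch]], mothers, pos_m_list[[ch]], L_m)
      g2 <- gamete_block(haps[[ch]], fathers, pos_m_list[[ch]], L_m)
      nh <- matrix(0L, 2L * ne, ncol(haps[[ch]]))
      nh[seq(1L, 2L * ne, 2L), ] <- g1
      nh[seq(2L, 2L * ne, 2L), ] <- g2
      haps[[ch]] <- nh
    }
    if (!is.null(sweep_site) && is.na(fix_gen) &&
        sum(haps[[sweep_site$chrom]][, sweep_site$index]) == 2L * ne)
      fix_gen <- gen
  }
  lost <- FALSE
  if (!is.null(sweep_site)) {
    hc <- haps[[sweep_site$chrom]]
    lost <- sum(hc[, sweep_site$index]) == 0L
  }
  list(haps = haps, lost = lost, fix_gen = fix_gen)
}

#' @keywords internal
#' @noRd
simulate_once <- function(cfg, seed) {
  set.seed(seed)
  n_chrom <- cfg$n_chromosomes
  m <- cfg$n_snps_per_chrom
  pos_list <- lapply(seq_len(n_chrom), function(ch)
    sort(sample.int(cfg$chrom_length_bp, m)))
  L_m <- cfg$chrom_length_bp / 1e6 * cfg$recomb_cm_per_mb / 100
  pos_m_list <- lapply(pos_list, function(p) p / 1e6 * cfg$recomb_cm_per_mb / 100)
  p0_list <- lapply(seq_len(n_chrom), function(ch) {
    if (cfg$ancestral_freq == "beta") stats::rbeta(m, cfg$beta_a, cfg$beta_b)
    else stats::runif(m, cfg$unif_min, cfg$unif_max)
  })
  sweep_site <- NULL
  if (!is.null(cfg$sweep)) {
    idx <- which.min(abs(pos_list[[cfg$sweep$chrom]] - cfg$sweep$pos))
    if (!is.null(cfg$sweep$initial_freq))
      p0_list[[cfg$sweep$chrom]][idx] <- cfg$sweep$initial_freq
    sweep_site <- list(chrom = cfg$sweep$chrom, index = idx, s = cfg$sweep$s,
                       start_generation = cfg$sweep$start_generation %||% 1L)
  }
  # one shared ancestral haplotype pool: every population is founded from the
  # same generation-0 pool (copies for equal Ne), so divergence measures only
  # drift after the split, not the founding draw
  max_ne <- max(cfg$ne)
  anc <- lapply(seq_len(n_chrom), function(ch)
    matrix(stats::rbinom(2L * max_ne * m, 1L, rep(p0_list[[ch]], each = 2L * max_ne)),
           2L * max_ne, m))
  if (!is.null(sweep_site) && !is.null(cfg$sweep$initial_freq)) {
    n1 <- round(cfg$sweep$initial_freq * 2L * max_ne)
    col <- integer(2L * max_ne)
    col[sample.int(2L * max_ne, n1)] <- 1L
    anc[[sweep_site$chrom]][, sweep_site$index] <- col
  }
  pops <- vector("list", cfg$n_populations)
  for (pp in seq_len(cfg$n_populations)) {
    ne <- cfg$ne[pp]
    haps <- lapply(anc, function(A) A[seq_len(2L * ne), , drop = FALSE])
    ss <- if (!is.null(sweep_site) && pp == cfg$sweep$population) sweep_site else NULL
    ev <- evolve_population(haps, pos_m_list, L_m, ne, cfg$generations, ss)
    if (!is.null(ss) && ev$lost) return(list(lost = TRUE))
    if (!is.null(ss)) fix_gen <- ev$fix_gen
    pops[[pp]] <- ev$haps
  }
  fixed <- NA
  if (is.null(sweep_site)) fix_gen <- NA_integer_
  if (!is.null(sweep_site)) {
    hc <- pops[[cfg$sweep$population]][[sweep_site$chrom]]
    fixed <- mean(hc[, sweep_site$index]) == 1
  }
  list(lost = FALSE, pops = pops, pos_list = pos_list, p0_list = p0_list,
       anc_freq = lapply(anc, colMeans),
       sweep_site = sweep_site, sweep_fixed = fixed, sweep_fix_gen = fix_gen)
}

#' Simulate a multi-population dataset
#'
#' Runs the Wright-Fisher forward model described in [sim_config()], samples
#' the configured number of diploids from each population's final
#' generation, and assembles genotypes, phased haplotypes and a truth
#' record.
#'
#' @param cfg from [sim_config()].
#' @return object of class `sim_dataset`: list(genotypes, haplotypes =
#'   per-chromosome `haplotypes` objects covering all samples, truth).
#'   Population labels are "pop1", "pop2", ...; sample ids
#'   "pop1_1", ....
#' @export
simulate_dataset <- function(cfg) {
  seed <- cfg$seed
  attempt <- 0L
  repeat {
    res <- simulate_once(cfg, seed)
    cond <- !is.null(cfg$sweep) && isTRUE(cfg$sweep$condition_on_fixation)
    fix_by <- cfg$sweep$fix_by_generation %||% cfg$generations
    fix_after <- cfg$sweep$fix_after_generation %||% 0L
    ok <- !res$lost &&
      (!cond || (isTRUE(res$sweep_fixed) &&
                   !is.na(res$sweep_fix_gen) &&
                   res$sweep_fix_gen <= fix_by &&
                   res$sweep_fix_gen > fix_after))
    if (ok) break
    attempt <- attempt + 1L
    if (attempt > cfg$max_retries)
      ps_stop("simulate_dataset: sweep conditioning failed after %d retries",
              cfg$max_retries)
    seed <- seed + 1L
  }
  if (attempt > 0L)
    message(sprintf("simulate_dataset: conditioning took %d retr%s (final seed %d)",
                    attempt, if (attempt == 1L) "y" else "ies", seed))
  n_chrom <- cfg$n_chromosomes
  pop_labels <- paste0("pop", seq_len(cfg$n_populations))
  sample_ids <- list(); sampled_rows <- list()
  for (pp in seq_len(cfg$n_populations)) {
    idx <- sort(sample.int(cfg$ne[pp], cfg$sample_sizes[pp]))
    sample_ids[[pp]] <- paste0(pop_labels[pp], "_", seq_along(idx))
    sampled_rows[[pp]] <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  }
  variants_list <- lapply(seq_len(n_chrom), function(ch) {
    data.frame(snp_id = sprintf("chr%d_%d", ch, res$pos_list[[ch]]),
               chrom = paste0("chr", ch), pos = res$pos_list[[ch]],
               allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
  })
  haps_objects <- list()
  dosage_blocks <- vector("list", n_chrom)
  all_ids <- unlist(sample_ids)
  soh <- rep(all_ids, each = 2L)
  for (ch in seq_len(n_chrom)) {
    hb <- do.call(rbind, lapply(seq_len(cfg$n_populations), function(pp)
      res$pops[[pp]][[ch]][sampled_rows[[pp]], , drop = FALSE]))
    haps_objects[[paste0("chr", ch)]] <-
      new_haplotypes(hb, variants_list[[ch]], soh)
    odd <- seq(1L, nrow(hb), 2L)
    dosage_blocks[[ch]] <- hb[odd, , drop = FALSE] + hb[odd + 1L, , drop = FALSE]
  }
  dosage <- do.call(cbind, dosage_blocks)
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < cfg$missing_rate
    dosage[mask] <- NA_integer_
  }
  samples <- data.frame(sample_id = all_ids,
                        population = rep(pop_labels, cfg$sample_sizes),
                        stringsAsFactors = FALSE)
  g <- new_genotypes(dosage, do.call(rbind, variants_list), samples)
  truth <- list(config = cfg, seed_used = seed,
                ancestral_freq = lapply(seq_len(n_chrom), function(ch)
                  stats::setNames(res$anc_freq[[ch]],
                                  variants_list[[ch]]$snp_id)),
                pedigree = data.frame(sample_id = character(0),
                                      parent1 = character(0),
                                      parent2 = character(0),
                                      stringsAsFactors = FALSE))
  if (!is.null(res$sweep_site)) {
    ss <- res$sweep_site
    v <- variants_list[[ss$chrom]]
    truth$sweep <- list(snp_id = v$snp_id[ss$index], chrom = v$chrom[ss$index],
                        pos = v$pos[ss$index], s = ss$s,
                        population = pop_labels[cfg$sweep$population],
                        fixed = res$sweep_fixed,
                        fix_generation = res$sweep_fix_gen)
  }
  structure(list(genotypes = g, haplotypes = haps_objects, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d population(s), %d samples, %d SNPs on %d chromosome(s)%s\n",
              x$truth$config$n_populations, nrow(x$genotypes$dosage),
              ncol(x$genotypes$dosage), x$truth$config$n_chromosomes,
              if (!is.null(x$truth$sweep)) sprintf("; sweep at %s", x$truth$sweep$snp_id) else ""))
  invisible(x)
}

#' Plant related individuals into a simulated dataset
#'
#' Adds samples constructed from existing samples' haplotypes: offspring by
#' Mendelian transmission with recombination from two named parents, or
#' exact duplicates. The truth pedigree is extended.
#'
#' @param dataset a `sim_dataset`.
#' @param spec data.frame with columns `new_id`, `type` ("offspring" or
#'   "duplicate"), `parent1`, `parent2` (`parent2` ignored for
#'   duplicates). Rows are processed in order, so offspring can be used as
#'   parents of later rows (e.g. to mate two full sibs).
#' @param seed RNG seed for the transmissions.
#' @return updated `sim_dataset`.
#' @export
plant_relatives <- function(dataset, spec, seed = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"))
  set.seed(seed)
  cfg <- dataset$truth$config
  g <- dataset$genotypes
  haps <- dataset$haplotypes
  L_m <- cfg$chrom_length_bp / 1e6 * cfg$recomb_cm_per_mb / 100
  for (i in seq_len(nrow(spec))) {
    type <- spec$type[i]; nid <- spec$new_id[i]
    p1 <- spec$parent1[i]
    if (!p1 %in% g$samples$sample_id) ps_stop("unknown parent id: %s", p1)
    pop1 <- g$samples$population[match(p1, g$samples$sample_id)]
    new_dosage_chr <- list()
    for (ch in names(haps)) {
      h <- haps[[ch]]
      pos_m <- h$variants$pos / 1e6 * cfg$recomb_cm_per_mb / 100
      r1 <- which(h$sample_of_haplotype == p1)
      if (type == "duplicate") {
        new_rows <- h$haplos[r1, , drop = FALSE]
      } else {
        p2 <- spec$parent2[i]
        if (!p2 %in% g$samples$sample_id) ps_stop("unknown parent id: %s", p2)
        r2 <- which(h$sample_of_haplotype == p2)
        H1 <- h$haplos[r1, , drop = FALSE]
        H2 <- h$haplos[r2, , drop = FALSE]
        gam1 <- gamete_block(H1, 1L, pos_m, L_m)
        gam2 <- gamete_block(H2, 1L, pos_m, L_m)
        new_rows <- rbind(gam1, gam2)
      }
      haps[[ch]] <- new_haplotypes(rbind(h$haplos, new_rows), h$variants,
                                   c(h$sample_of_haplotype, nid, nid))
      new_dosage_chr[[ch]] <- stats::setNames(colSums(new_rows),
                                              h$variants$snp_id)
    }
    new_dos <- unlist(unname(new_dosage_chr))[colnames(g$dosage)]
    g <- new_genotypes(rbind(g$dosage, new_dos),
                       g$variants,
                       rbind(g$samples,
                             data.frame(sample_id = nid, population = pop1,
                                        stringsAsFactors = FALSE)))
    dataset$truth$pedigree <- rbind(
      dataset$truth$pedigree,
      data.frame(sample_id = nid, parent1 = p1,
                 parent2 = if (type == "duplicate") p1 else spec$parent2[i],
                 stringsAsFactors = FALSE))
  }
  dataset$genotypes <- g
  dataset$haplotypes <- haps
  dataset
}

#' Export a simulated dataset
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @param format "plink_text" or "vcf_phased".
#' @return paths of the written files (genotypes plus `truth.json`).
#' @export
export_dataset <- function(dataset, dir, format = c("plink_text", "vcf_phased")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (format == "plink_text") {
    paths <- write_plink_text(dataset$genotypes, file.path(dir, "genotypes"))
  } else {
    if (anyNA(dataset$genotypes$dosage))
      ps_stop("export_dataset: phased VCF export requires complete genotypes")
    p <- file.path(dir, "genotypes.vcf")
    write_vcf_phased(dataset$haplotypes, p)
    paths <- p
  }
  truth_path <- file.path(dir, "truth.json")
  tr <- dataset$truth
  tr$config$sweep <- tr$config$sweep %||% NULL
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  c(paths, truth_path)
}
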