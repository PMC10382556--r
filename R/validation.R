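# Validation suite: the package's simulation-based calibration checks.
# Each function builds its stated world from scratch with the given seed,
# runs the relevant pipeline stage, and returns the measured quantity.
# The worlds (sizes, divergence times, sweep conditioning) are documented in
# the methods vignette; they are fixed properties of the checks, not tuning
# knobs.

#' @keywords internal
#' @noRd
acc_seed <- function(seed, rep, offset) {
  as.integer((as.numeric(seed) * 97L + offset * 1000003 + rep * 1009) %% 2147483647)
}

#' Drift calibration of multilocus FST
#'
#' Two populations, Ne = 100, t = 20 generations, 5000 SNPs, 50 diploids
#' sampled per population; the multilocus Weir-Cockerham estimate is
#' compared with the drift expectation `1 - (1 - 1/(2 Ne))^t`.
#'
#' @param seed integer seed.
#' @param n_reps replicates (default 20).
#' @return list(mean_theta, se, expected, thetas).
#' @export
acc_drift_calibration <- function(seed, n_reps = 20L) {
  thetas <- vapply(seq_len(n_reps), function(r) {
    ds <- simulate_dataset(sim_config(seed = acc_seed(seed, r, 1L),
                                      n_populations = 2, ne = 100L,
                                      generations = 20L, n_chromosomes = 5L,
                                      n_snps_per_chrom = 1000L,
                                      chrom_length_bp = 5e7,
                                      sample_sizes = 50L))
    pairwise_fst_multilocus(ds$genotypes, "pop1", "pop2", n_boot = 100L,
                            seed = r)$theta
  }, numeric(1))
  list(mean_theta = mean(thetas),
       se = stats::sd(thetas) / sqrt(n_reps),
       expected = 1 - (1 - 1 / 200)^20,
       thetas = thetas)
}

#' FLK null calibration against the chi-squared distribution
#'
#' A matched neutral world in the small-kinship regime where the Gaussian
#' drift model holds: Ne = 500, t = 20 (f = 0.0198), 10 chromosomes x 500
#' SNPs, Uniform(0.2, 0.8) ancestral frequencies, the whole final
#' generation sampled. The FLK statistic over ~5000 SNPs is compared to
#' chi-squared(1) by a KS test.
#'
#' @param seed integer seed.
#' @return list(ks_p, ks_D, n, mean_stat).
#' @export
acc_flk_null <- function(seed) {
  ds <- simulate_dataset(sim_config(seed = acc_seed(seed, 1L, 2L),
                                    n_populations = 2, ne = 500L,
                                    generations = 20L, n_chromosomes = 10L,
                                    n_snps_per_chrom = 500L,
                                    chrom_length_bp = 5e7,
                                    ancestral_freq = "uniform",
                                    unif_min = 0.2, unif_max = 0.8,
                                    sample_sizes = 500L))
  p <- allele_frequencies(ds$genotypes)$p
  ok <- !is.na(p[1, ]) & !is.na(p[2, ]) & colMeans(p) > 0 & colMeans(p) < 1
  f <- 1 - (1 - 1 / 1000)^20
  F <- diag(c(f, f))
  dimnames(F) <- list(c("pop1", "pop2"), c("pop1", "pop2"))
  stat <- flk_test(p[, ok], F)$stat
  stat <- stat[!is.na(stat)]
  ks <- suppressWarnings(stats::ks.test(stat, "pchisq", df = 1))
  list(ks_p = unname(ks$p.value), ks_D = unname(ks$statistic),
       n = length(stat), mean_stat = mean(stat))
}

#' @keywords internal
#' @noRd
acc_scan_world <- function(seed, sweep) {
  sw <- if (sweep) list(population = 1, chrom = 1, pos = 3e7, s = 0.1,
                        start_generation = 1, initial_freq = 1 / 400,
                        condition_on_fixation = TRUE,
                        fix_by_generation = 90, fix_after_generation = 60)
  cfg <- sim_config(seed = seed, n_populations = 2, ne = 200L,
                    generations = 90L, n_chromosomes = 1L,
                    n_snps_per_chrom = 2500L, chrom_length_bp = 6e7,
                    sample_sizes = 30L, sweep = sw, max_retries = 300L)
  suppressMessages(simulate_dataset(cfg))
}

#' False-discovery control of the DCMS scan on neutral simulations
#'
#' Null world matched to the sweep world minus selection (Ne = 200, t = 90,
#' one 60-Mbps chromosome of 2500 SNPs, 30 diploids per population); counts
#' replicates with zero q < 0.05 SNPs in the primary orientation.
#'
#' @param seed integer seed.
#' @param n_reps replicates (default 20).
#' @return list(n_clean, n_reps, n_significant per replicate).
#' @export
acc_fdr_null <- function(seed, n_reps = 20L) {
  nsig <- vapply(seq_len(n_reps), function(r) {
    ds <- acc_scan_world(acc_seed(seed, r, 3L), sweep = FALSE)
    sc <- run_pairwise_scan(ds$genotypes, ds$haplotypes, "pop1", "pop2",
                            scan_config(seed = acc_seed(seed, r, 4L)))
    sum(sc$significant, na.rm = TRUE)
  }, numeric(1))
  list(n_clean = sum(nsig == 0), n_reps = n_reps, n_significant = nsig)
}

#' Power and localization of the DCMS scan for a hard sweep
#'
#' The sweep world adds a de novo single-copy mutation (s = 0.1) at the
#' chromosome midpoint of population 1, conditioned to fix in generations
#' (60, 90]; a replicate is a hit when a significant SNP lies within
#' 500 kbps of the true site.
#'
#' @param seed integer seed.
#' @param n_reps replicates (default 10).
#' @return list(n_hits, n_reps, dist_bp nearest significant SNP distances).
#' @export
acc_sweep_power <- function(seed, n_reps = 10L) {
  dist <- vapply(seq_len(n_reps), function(r) {
    ds <- acc_scan_world(acc_seed(seed, r, 5L), sweep = TRUE)
    sc <- run_pairwise_scan(ds$genotypes, ds$haplotypes, "pop1", "pop2",
                            scan_config(seed = acc_seed(seed, r, 6L)))
    sig <- sc[sc$significant & !is.na(sc$significant), , drop = FALSE]
    if (nrow(sig) == 0L) return(Inf)
    min(abs(sig$pos - ds$truth$sweep$pos))
  }, numeric(1))
  list(n_hits = sum(dist <= 5e5), n_reps = n_reps, dist_bp = dist)
}

#' Recovery of contemporary Ne from inter-chromosomal LD
#'
#' True Ne = 100, t = 20 generations, 4 chromosomes x 500 SNPs, 50 diploids
#' sampled; reports the median LD-Ne estimate (MAF screen 0.05).
#'
#' @param seed integer seed.
#' @param n_reps replicates (default 20).
#' @return list(median_ne, estimates).
#' @export
acc_ne_recovery <- function(seed, n_reps = 20L) {
  nes <- vapply(seq_len(n_reps), function(r) {
    ds <- simulate_dataset(sim_config(seed = acc_seed(seed, r, 7L),
                                      n_populations = 1, ne = 100L,
                                      generations = 20L, n_chromosomes = 4L,
                                      n_snps_per_chrom = 500L,
                                      chrom_length_bp = 5e7,
                                      sample_sizes = 50L))
    contemporary_ldne(ds$genotypes, "pop1", maf_screen = 0.05)$ne_point
  }, numeric(1))
  list(median_ne = stats::median(nes), estimates = nes)
}

#' Inbreeding contrast of F_ROH between full-sib offspring and outbred peers
#'
#' Each replicate simulates one population (Ne = 100, t = 30, two 30-Mbps
#' chromosomes of 1500 SNPs), plants two independent full-sib matings and
#' their offspring, and compares the inbred offspring's F_ROH with the
#' outbred sample mean.
#'
#' @param seed integer seed.
#' @param n_reps replicates (default 20).
#' @return list(mean_diff, diffs).
#' @export
acc_roh_contrast <- function(seed, n_reps = 20L) {
  diffs <- vapply(seq_len(n_reps), function(r) {
    ds <- simulate_dataset(sim_config(seed = acc_seed(seed, r, 8L),
                                      n_populations = 1, ne = 100L,
                                      generations = 30L, n_chromosomes = 2L,
                                      n_snps_per_chrom = 1500L,
                                      chrom_length_bp = 3e7,
                                      sample_sizes = 12L))
    spec <- data.frame(
      new_id = c("a_sib1", "a_sib2", "a_inbred", "b_sib1", "b_sib2", "b_inbred"),
      type = "offspring",
      parent1 = c("pop1_1", "pop1_1", "a_sib1", "pop1_3", "pop1_3", "b_sib1"),
      parent2 = c("pop1_2", "pop1_2", "a_sib2", "pop1_4", "pop1_4", "b_sib2"),
      stringsAsFactors = FALSE)
    ds2 <- plant_relatives(ds, spec, seed = acc_seed(seed, r, 9L))
    g <- ds2$genotypes
    segs <- detect_roh(g)
    glen <- map_genome_length(g)
    fr <- vapply(g$samples$sample_id, function(s)
      froh(segs[segs$sample_id == s, , drop = FALSE], glen), numeric(1))
    mean(fr[c("a_inbred", "b_inbred")]) - mean(fr[paste0("pop1_", 5:12)])
  }, numeric(1))
  list(mean_diff = mean(diffs), diffs = diffs)
}

#' Exact worked identities of the statistic stack
#'
#' Deterministic spot checks: DCMS de-correlation of a duplicated
#' statistic, xp-EHH antisymmetry, FLK at equal frequencies, the AFD worked
#' example, the exact HWE p at counts (1,0,1), and the BH fixture.
#'
#' @param seed integer seed (fixtures are deterministic; the seed feeds the
#'   random duplicated-statistic vector).
#' @return named list of measured values.
#' @export
acc_exact_identities <- function(seed = 1L) {
  set.seed(seed)
  p <- runif(200, 0.001, 0.999)
  dup_err <- max(abs(dcms(cbind(p, p), matrix(1, 2, 2)) -
                       dcms(matrix(p, ncol = 1), matrix(1, 1, 1))))
  set.seed(seed + 1)
  v <- data.frame(snp_id = paste0("m", 1:40), chrom = "chr1",
                  pos = seq_len(40) * 10000L, allele_a = "A", allele_b = "C",
                  stringsAsFactors = FALSE)
  ha <- new_haplotypes(matrix(rbinom(20 * 40, 1, 0.5), 20, 40), v,
                       rep(paste0("a", 1:10), each = 2))
  hb <- new_haplotypes(matrix(rbinom(20 * 40, 1, 0.5), 20, 40), v,
                       rep(paste0("b", 1:10), each = 2))
  ab <- xpehh(ha, hb, max_gap_bp = 1e9)
  ba <- xpehh(hb, ha, max_gap_bp = 1e9)
  ok <- !is.na(ab)
  xp_err <- max(abs(ab[ok] + ba[ok]))
  F <- diag(c(0.05, 0.05)); dimnames(F) <- list(c("A", "B"), c("A", "B"))
  flk0 <- flk_test(c(A = 0.37, B = 0.37), F)$stat
  flk_hand <- flk_test(c(A = 0.9, B = 0.1), F)$stat
  fr <- list(p = rbind(A = 0.8, B = 0.3), n_called = rbind(A = 50, B = 50),
             populations = c("A", "B"))
  rownames(fr$p) <- rownames(fr$n_called) <- c("A", "B")
  afd_val <- afd(fr, "A", "B")$per_snp[[1]]
  hwe_p <- hwe_exact_test(1, 0, 1)
  bh_q <- bh_fdr(c(0.01, 0.02, 0.03, 0.9))$q
  list(dcms_dup_max_abs_err = dup_err,
       xpehh_antisym_max_abs_err = xp_err,
       flk_equal_freq_stat = flk0,
       flk_hand_stat = flk_hand,
       afd_worked_example = afd_val,
       hwe_p_101 = hwe_p,
       bh_q_fixture = bh_q)
}
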