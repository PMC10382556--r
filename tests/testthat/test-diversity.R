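# differentiation and diversity statistics

toy_two_pop <- function(dA, dB) {
  d <- rbind(dA, dB)
  toy_genotypes(d, populations = rep(c("A", "B"), c(nrow(dA), nrow(dB))))
}

test_that("allele frequencies are per-population allele_b fractions", {
  g <- toy_two_pop(rbind(c(2L, 0L, 1L), c(2L, 1L, NA)),
                   rbind(c(0L, 2L, 0L), c(0L, 1L, 0L)))
  fr <- allele_frequencies(g)
  expect_equal(unname(fr$p["A", ]), c(1, 0.25, 0.5))
  expect_equal(unname(fr$p["B", ]), c(0, 0.75, 0))
  expect_equal(unname(fr$n_called["A", 3]), 1L)
  # population with no called genotype at a SNP -> NA
  g2 <- toy_two_pop(rbind(c(NA_integer_, 1L)), rbind(c(2L, 1L)))
  expect_true(is.na(allele_frequencies(g2)$p["A", 1]))
})

test_that("AFD matches the worked identities", {
  g <- toy_two_pop(rbind(c(2L, 2L, 2L), c(2L, 2L, 1L)),
                   rbind(c(2L, 0L, 0L), c(2L, 0L, 1L)))
  fr <- allele_frequencies(g)
  res <- afd(fr, "A", "B")
  expect_equal(unname(res$per_snp), c(0, 1, 0.5))   # identity, fixation, 0.8-0.3
  expect_equal(res$mean, 0.5)
  expect_true(all(res$per_snp >= 0 & res$per_snp <= 1))
})

test_that("chord distance: zero on identity, closed form for opposite fixation", {
  g_same <- toy_two_pop(rbind(c(1L, 1L)), rbind(c(1L, 1L)))
  expect_equal(chord_distance(allele_frequencies(g_same), "A", "B"), 0)
  g_fix <- toy_two_pop(rbind(c(2L, 2L)), rbind(c(0L, 0L)))   # wait: single locus case below
  g_fix1 <- toy_two_pop(rbind(2L), rbind(0L))
  expect_equal(chord_distance(allele_frequencies(g_fix1), "A", "B"),
               2 * sqrt(2) / pi, tolerance = 1e-12)
  # monotonicity: widening |p1 - p2| at one locus never decreases D
  base <- seq(0, 0.5, by = 0.05)
  ds <- vapply(base, function(delta) {
    fr <- list(p = rbind(A = c(0.5, 0.5), B = c(0.5 + delta, 0.5)),
               n_called = rbind(A = c(50, 50), B = c(50, 50)),
               populations = c("A", "B"))
    chord_distance(fr, "A", "B")
  }, numeric(1))
  expect_true(all(diff(ds) >= -1e-12))
})

test_that("Reynolds distance is near zero for identical populations and symmetric", {
  set.seed(2)
  d <- matrix(rbinom(40 * 400, 2, rep(runif(400, 0.2, 0.8), each = 40)), 40, 400)
  g <- toy_genotypes(d, populations = rep(c("A", "B"), each = 20))
  fr <- allele_frequencies(g)
  expect_lt(abs(reynolds_distance(fr, "A", "B")), 0.01)
  expect_equal(reynolds_distance(fr, "A", "B"), reynolds_distance(fr, "B", "A"))
})

test_that("Reynolds distance tracks -ln(1 - E[FST]) under drift", {
  vals <- vapply(1:6, function(r) {
    ds <- simulate_dataset(sim_config(seed = 40 + r, n_populations = 2,
                                      ne = 100, generations = 20,
                                      n_chromosomes = 4, n_snps_per_chrom = 500,
                                      sample_sizes = 50))
    reynolds_distance(allele_frequencies(ds$genotypes), "pop1", "pop2")
  }, numeric(1))
  target <- -log(1 - (1 - (1 - 1 / 200)^20))
  expect_lt(abs(mean(vals) - target), 3 * sd(vals) / sqrt(length(vals)) + 0.01)
})

test_that("per-SNP Weir-Cockerham theta matches hand and independent evaluation", {
  # p1=1, p2=0, n=50 each, no heterozygotes -> theta = 1
  g <- toy_two_pop(matrix(2L, 50, 1), matrix(0L, 50, 1))
  expect_equal(unname(per_snp_wc_fst(g, "A", "B")), 1)
  # identical genotype counts -> no among-population variance, theta <= 0
  block <- matrix(rep(c(0L, 1L, 2L), length.out = 30), 30, 1)
  g2 <- toy_two_pop(block, block)
  expect_lte(unname(per_snp_wc_fst(g2, "A", "B")), 0)
  # random fixture vs an independently coded WC(1984) implementation
  set.seed(31)
  d <- rbind(matrix(rbinom(20 * 8, 2, 0.3), 20, 8),
             matrix(rbinom(25 * 8, 2, 0.6), 25, 8))
  g3 <- toy_genotypes(d, populations = rep(c("A", "B"), c(20, 25)))
  mine <- per_snp_wc_fst(g3, "A", "B")
  oracle <- vapply(seq_len(8), function(j) {
    x <- d[1:20, j]; y <- d[21:45, j]
    n1 <- 20; n2 <- 25; r <- 2
    p1 <- mean(x) / 2; p2 <- mean(y) / 2
    h1 <- mean(x == 1); h2 <- mean(y == 1)
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
  }, numeric(1))
  expect_equal(unname(mine), oracle, tolerance = 1e-12)
})

test_that("multilocus FST equals per-SNP value at M=1 and its CI tightens with M", {
  # ratio-of-sums over one locus duplicated equals the per-SNP estimate
  colA <- c(rep(0L, 10), rep(1L, 10)); colB <- c(rep(2L, 10), rep(1L, 10))
  g <- toy_two_pop(cbind(colA, colA), cbind(colB, colB))
  f1 <- pairwise_fst_multilocus(g, "A", "B", n_boot = 100, seed = 2)
  theta_single <- unname(per_snp_wc_fst(g, "A", "B")[1])
  expect_equal(f1$theta, theta_single, tolerance = 1e-12)
  ds <- simulate_dataset(sim_config(seed = 77, n_populations = 2, ne = 80,
                                    generations = 15, n_chromosomes = 4,
                                    n_snps_per_chrom = 750, sample_sizes = 30))
  g_small <- subset_genotypes(ds$genotypes, snps = 1:300)
  fs <- pairwise_fst_multilocus(g_small, "pop1", "pop2", n_boot = 300, seed = 3)
  fl <- pairwise_fst_multilocus(ds$genotypes, "pop1", "pop2", n_boot = 300, seed = 3)
  expect_lt(fl$ci_high - fl$ci_low, fs$ci_high - fs$ci_low)
  # identical populations: theta <= 0 with CI covering 0
  set.seed(11)
  d <- matrix(rbinom(60 * 300, 2, rep(runif(300, 0.2, 0.8), each = 60)), 60, 300)
  g_id <- toy_genotypes(d, populations = rep(c("A", "B"), each = 30))
  f0 <- pairwise_fst_multilocus(g_id, "A", "B", n_boot = 200, seed = 4)
  expect_lte(f0$ci_low, 0)
  expect_gte(f0$ci_high, f0$theta)
})

test_that("zfst standardizes to mean 0 / sd 1 and is shift/scale stable", {
  x <- c(0.1, 0.4, 0.2, NA, 0.9, 0.05)
  z <- zfst(x)
  ok <- !is.na(z)
  expect_equal(mean(z[ok]), 0, tolerance = 1e-9)
  expect_equal(sd(z[ok]), 1, tolerance = 1e-9)
  expect_equal(zfst(x + 5), z, tolerance = 1e-9)
  expect_equal(zfst(x * 7), z, tolerance = 1e-9)
  expect_error(zfst(rep(0.3, 4)), "zero variance")
})

test_that("LD decay curve: single pair bin equals ld_r2; drift data decay monotonically", {
  g <- toy_genotypes(cbind(c(0L, 1L, 2L, 1L, 0L), c(0L, 1L, 1L, 2L, 0L)),
                     pos = c(10000L, 60000L))
  curve <- ld_decay_curve(g, max_dist_bp = 2e5, bin_width_bp = 1e5)
  expect_equal(curve$mean_r2[1], ld_r2(g, 1, 2))
  expect_equal(curve$n_pairs[1], 1L)
  # simulated recombining population: negative Spearman trend across bins
  ds <- simulate_dataset(sim_config(seed = 55, n_populations = 1, ne = 80,
                                    generations = 30, n_chromosomes = 2,
                                    n_snps_per_chrom = 400, chrom_length_bp = 2e7,
                                    sample_sizes = 40))
  cv <- ld_decay_curve(ds$genotypes, max_dist_bp = 2e6, bin_width_bp = 2e5)
  ok <- !is.na(cv$mean_r2)
  expect_lt(cor(cv$bin_start[ok], cv$mean_r2[ok], method = "spearman"), 0)
  # permuted genotypes: LD destroyed, curve flat near the 1/N background
  gp <- ds$genotypes
  set.seed(1)
  gp$dosage <- apply(gp$dosage, 2, sample)
  cvp <- ld_decay_curve(gp, max_dist_bp = 2e6, bin_width_bp = 2e5)
  okp <- !is.na(cvp$mean_r2)
  expect_lt(max(cvp$mean_r2[okp]), 5 / nrow(gp$dosage))
})

test_that("distance matrices are symmetric with zero diagonal", {
  ds <- simulate_dataset(sim_config(seed = 14, n_populations = 3, ne = 50,
                                    generations = 10, n_chromosomes = 2,
                                    n_snps_per_chrom = 150, sample_sizes = 20))
  fr <- allele_frequencies(ds$genotypes)
  for (metric in c("chord", "reynolds", "afd_mean")) {
    m <- distance_matrix(fr, metric)
    expect_equal(unname(diag(m)), rep(0, 3))
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_true(all(m >= 0))
  }
})

test_that("differentiation grows with divergence time", {
  stats_at_t <- function(t, reps = 4) {
    vapply(seq_len(reps), function(r) {
      ds <- simulate_dataset(sim_config(seed = 1000 * t + r, n_populations = 2,
                                        ne = 60, generations = t,
                                        n_chromosomes = 2, n_snps_per_chrom = 400,
                                        sample_sizes = 30))
      fr <- allele_frequencies(ds$genotypes)
      c(afd(fr, "pop1", "pop2")$mean,
        pairwise_fst_multilocus(ds$genotypes, "pop1", "pop2",
                                n_boot = 100, seed = r)$theta,
        reynolds_distance(fr, "pop1", "pop2"))
    }, numeric(3))
  }
  m5 <- rowMeans(stats_at_t(5)); m20 <- rowMeans(stats_at_t(20))
  m80 <- rowMeans(stats_at_t(80))
  expect_true(all(m5 < m20 & m20 < m80))
})
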