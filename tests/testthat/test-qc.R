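# QC cascade: call rate, exact HWE, MAF filter, IBD, LD pruning

test_that("call-rate filter removes SNPs first, then samples", {
  d <- matrix(1L, 10, 10)
  d[1:2, 1] <- NA       # SNP 1: 80% call rate
  d[1, 2:3] <- NA       # sample 1: low call rate after SNP 1 is gone
  g <- toy_genotypes(d)
  res <- filter_call_rate(g, 0.9)
  expect_equal(res$report$n_snps_removed, 1L)
  expect_equal(res$report$n_samples_removed, 1L)
  expect_false("snp1" %in% res$genotypes$variants$snp_id)
  expect_false("s1" %in% res$genotypes$samples$sample_id)
  # complete matrix: identity
  res2 <- filter_call_rate(toy_genotypes(matrix(1L, 4, 4)), 0.9)
  expect_equal(res2$report$n_snps_removed, 0L)
  expect_equal(res2$report$n_samples_removed, 0L)
})

test_that("exact HWE test matches enumeration and known values", {
  # (1,0,1): het counts 0 or 2 with P(0) = 1/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # modal configuration has the largest probability, so its p is maximal
  p_modal <- hwe_exact_test(25, 50, 25)
  for (h in c(40, 46, 54, 60)) {
    aa <- (100 - h) / 2; bb <- (100 - h) / 2
    expect_lte(hwe_exact_test(aa, h, bb), p_modal + 1e-12)
  }
  # extreme heterozygote excess is vanishingly unlikely
  expect_lt(hwe_exact_test(0, 50, 0), 1e-6)
  # agreement with the independent enumeration oracle over assorted counts
  for (cfg in list(c(3, 5, 2), c(0, 2, 8), c(10, 1, 10), c(7, 7, 7),
                   c(0, 50, 0), c(20, 10, 20))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-9)
  }
  # monomorphic SNP: p = 1 by convention
  expect_equal(hwe_exact_test(10, 0, 0), 1)
})

test_that("HWE probabilities sum to one over the conditional distribution", {
  for (n in c(5, 17, 50)) {
    n_a <- n; n_b <- n          # equal allele counts, n diploids
    hets <- seq(n_a %% 2, n_a, by = 2)
    w <- vapply(hets, function(h) {
      aa <- (n_a - h) / 2; bb <- (n_b - h) / 2
      exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
            h * log(2))
    }, numeric(1))
    expect_equal(sum(w / sum(w)), 1, tolerance = 1e-9)
  }
})

test_that("MAF/HWE filter applies strict thresholds", {
  set.seed(1)
  n <- 200
  d <- cbind(
    rbinom(n, 2, 0.5),                       # fine
    c(rep(1L, 2), rep(0L, n - 2)),           # MAF 0.005 < 0.01 -> removed
    c(rep(1L, 4), rep(0L, n - 4)),           # MAF exactly 0.01 -> retained
    rep(1L, n))                              # all het: HWE violation
  g <- toy_genotypes(d)
  res <- filter_maf_hwe(g, min_maf = 0.01, hwe_alpha = 1e-6)
  kept <- res$genotypes$variants$snp_id
  expect_true("snp1" %in% kept)
  expect_false("snp2" %in% kept)
  expect_true("snp3" %in% kept)
  expect_false("snp4" %in% kept)
  expect_equal(res$report$detail$n_hwe, 1L)
})

test_that("IBD method-of-moments recovers duplicate, unrelated and parent-offspring", {
  cfg <- sim_config(seed = 21, n_populations = 1, ne = 200, generations = 2,
                    n_chromosomes = 5, n_snps_per_chrom = 1000,
                    chrom_length_bp = 5e7, sample_sizes = 20)
  ds <- simulate_dataset(cfg)
  ds <- plant_relatives(ds, data.frame(
    new_id = c("dup", "kid"), type = c("duplicate", "offspring"),
    parent1 = c("pop1_1", "pop1_2"), parent2 = c(NA, "pop1_3")), seed = 4)
  pairs <- estimate_ibd(ds$genotypes)
  key <- function(a, b) which((pairs$sample_i == a & pairs$sample_j == b) |
                                (pairs$sample_i == b & pairs$sample_j == a))
  expect_gte(pairs$pi_hat[key("pop1_1", "dup")], 0.99)
  expect_lt(abs(pairs$pi_hat[key("pop1_2", "kid")] - 0.5), 0.05)
  expect_true(all(abs(pairs$p_ibd0 + pairs$p_ibd1 + pairs$p_ibd2 - 1) < 1e-9))
  expect_true(all(abs(pairs$pi_hat - (pairs$p_ibd2 + pairs$p_ibd1 / 2)) < 1e-9))
})

test_that("independent HWE draws at known frequencies have pi_hat near zero", {
  set.seed(77)
  m <- 5000
  p <- runif(m, 0.1, 0.9)
  d <- t(vapply(1:6, function(i) rbinom(m, 2, p), integer(m)))
  g <- toy_genotypes(d, chrom = rep("chr1", m), pos = seq_len(m) * 1000L)
  pairs <- estimate_ibd(g, freqs = p)
  expect_lt(max(abs(pairs$pi_hat)), 0.05)
})

test_that("greedy relatedness pruning removes the minimum sensible set", {
  g <- toy_genotypes(matrix(rep(0:1, 12), 4, 6), populations = rep("p", 4))
  mk_pairs <- function(df) {
    base <- expand.grid(i = 1:4, j = 1:4)
    base <- base[base$i < base$j, ]
    out <- data.frame(sample_i = paste0("s", base$i),
                      sample_j = paste0("s", base$j), pi_hat = 0)
    for (k in seq_len(nrow(df)))
      out$pi_hat[out$sample_i == df$i[k] & out$sample_j == df$j[k]] <- df$v[k]
    out
  }
  # triangle s1-s2-s3: brute-force minimal vertex cover has size 2
  tri <- mk_pairs(data.frame(i = c("s1", "s1", "s2"),
                             j = c("s2", "s3", "s3"), v = 0.5))
  res <- prune_related(g, tri, 0.25)
  expect_equal(res$report$n_samples_removed, 2L)
  expect_true(all(res$genotypes$samples$sample_id %in% c("s4", "s1", "s2", "s3")))
  # one related pair: exactly one removed
  one <- mk_pairs(data.frame(i = "s1", j = "s2", v = 0.6))
  expect_equal(prune_related(g, one, 0.25)$report$n_samples_removed, 1L)
  # nothing above threshold: identity
  none <- mk_pairs(data.frame(i = "s1", j = "s2", v = 0.2))
  expect_equal(prune_related(g, none, 0.25)$report$n_samples_removed, 0L)
})

test_that("ld_r2 equals squared Pearson correlation over joint calls", {
  g <- toy_genotypes(cbind(c(0L, 1L, 2L, 0L, 1L), c(0L, 1L, 2L, 0L, 1L),
                           c(2L, 1L, 0L, 2L, 1L), c(0L, 0L, 2L, 2L, 1L)))
  expect_equal(ld_r2(g, 1, 2), 1)
  expect_equal(ld_r2(g, 1, 3), 1)     # reversed dosages: r = -1, r2 = 1
  expect_equal(ld_r2(g, 1, 4),
               cor(c(0, 1, 2, 0, 1), c(0, 0, 2, 2, 1))^2, tolerance = 1e-12)
  g2 <- toy_genotypes(cbind(c(1L, 1L, 1L), c(0L, 1L, 2L)))
  expect_true(is.na(ld_r2(g2, 1, 2)))   # monomorphic -> undefined
})

test_that("independent loci have r2 near the 1/N sampling background", {
  set.seed(5)
  n <- 500
  d <- matrix(rbinom(n * 40, 2, 0.5), n, 40)
  g <- toy_genotypes(d)
  r2s <- ld_r2_matrix(g$dosage)
  vals <- r2s[upper.tri(r2s)]
  # E[r2] ~ 1/(N-1); SE of the mean over ~800 pairs is small
  expect_lt(abs(mean(vals) - 1 / (n - 1)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("LD pruning removes one of a perfectly correlated pair and matches a greedy oracle", {
  set.seed(8)
  base <- rbinom(40, 2, 0.5)
  g <- toy_genotypes(cbind(base, base, rbinom(40, 2, 0.5)))
  res <- ld_prune(g, window_snps = 10L, step_snps = 5L, r2_max = 0.5)
  expect_equal(res$report$n_snps_removed, 1L)
  # all pairs below threshold: identity
  d2 <- matrix(rbinom(40 * 5, 2, 0.5), 40, 5)
  g2 <- toy_genotypes(d2)
  if (max(ld_r2_matrix(g2$dosage)[upper.tri(diag(5))], na.rm = TRUE) < 0.5)
    expect_equal(ld_prune(g2, 10L, 5L, 0.5)$report$n_snps_removed, 0L)
  # 10-SNP correlated fixture against an independently coded greedy oracle
  set.seed(42)
  z <- rbinom(60, 2, 0.5)
  noisy <- function(p) ifelse(runif(60) < p, z, rbinom(60, 2, 0.5))
  d3 <- cbind(z, noisy(0.9), noisy(0.2), noisy(0.95), rbinom(60, 2, 0.5),
              noisy(0.85), rbinom(60, 2, 0.5), noisy(0.1), z, rbinom(60, 2, 0.5))
  g3 <- toy_genotypes(d3)
  res3 <- ld_prune(g3, window_snps = 10L, step_snps = 5L, r2_max = 0.5)
  # oracle: same rule, written independently (single window covers all SNPs)
  p <- colMeans(d3) / 2; maf <- pmin(p, 1 - p)
  pos <- g3$variants$pos
  alive <- rep(TRUE, 10)
  repeat {
    r2 <- suppressWarnings(cor(d3[, alive, drop = FALSE]))^2
    diag(r2) <- NA
    if (all(is.na(r2)) || max(r2, na.rm = TRUE) <= 0.5) break
    ij <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
    ids <- which(alive)[ij]
    drop <- if (maf[ids[1]] < maf[ids[2]]) ids[1]
    else if (maf[ids[2]] < maf[ids[1]]) ids[2]
    else ids[which.max(pos[ids])]
    alive[drop] <- FALSE
  }
  expect_setequal(res3$genotypes$variants$snp_id,
                  g3$variants$snp_id[alive])
})

test_that("the QC cascade is a no-op on its own output when no samples dropped", {
  # idempotence holds whenever the first pass removes no samples (sample
  # removal changes the per-SNP statistics the thresholds act on)
  # unrelated-by-construction HWE draws: PI_HAT stays well below 0.25, so
  # no samples are removed and the precondition holds
  set.seed(13)
  m <- 800; n <- 30
  p <- runif(m, 0.1, 0.9)
  d <- t(vapply(seq_len(n), function(i) rbinom(m, 2, p), integer(m)))
  d[runif(length(d)) < 0.01] <- NA
  g <- toy_genotypes(d, populations = rep(c("A", "B"), each = 15),
                     chrom = rep(c("chr1", "chr2"), each = m / 2),
                     pos = rep(seq_len(m / 2) * 50000L, 2))
  q1 <- qc_cascade(g)
  expect_equal(q1$reports$call_rate$n_samples_removed, 0L)
  expect_equal(q1$reports$ibd_prune$n_samples_removed, 0L)
  q2 <- qc_cascade(q1$genotypes)
  expect_equal(dim(q2$genotypes$dosage), dim(q1$genotypes$dosage))
  expect_equal(q2$reports$call_rate$n_snps_removed, 0L)
  expect_equal(q2$reports$maf_hwe$n_snps_removed, 0L)
  expect_equal(q2$reports$ibd_prune$n_samples_removed, 0L)
})
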