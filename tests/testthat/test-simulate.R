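# Wright-Fisher simulator: determinism, drift calibration, sweeps,
# relatives, export round-trips

test_that("the same seed reproduces the dataset exactly", {
  cfg <- sim_config(seed = 101, n_populations = 2, ne = 40, generations = 10,
                    n_chromosomes = 2, n_snps_per_chrom = 80, sample_sizes = 12,
                    missing_rate = 0.03)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genotypes$dosage, d2$genotypes$dosage)
  expect_identical(d1$haplotypes$chr1$haplos, d2$haplotypes$chr1$haplos)
  d3 <- simulate_dataset(sim_config(seed = 102, n_populations = 2, ne = 40,
                                    generations = 10, n_chromosomes = 2,
                                    n_snps_per_chrom = 80, sample_sizes = 12))
  expect_false(identical(d1$genotypes$dosage[, 1:10], d3$genotypes$dosage[, 1:10]))
})

test_that("zero divergence yields near-zero differentiation", {
  thetas <- vapply(1:10, function(r) {
    ds <- simulate_dataset(sim_config(seed = 200 + r, n_populations = 2,
                                      ne = 60, generations = 0,
                                      n_chromosomes = 2, n_snps_per_chrom = 400,
                                      sample_sizes = 30))
    pairwise_fst_multilocus(ds$genotypes, "pop1", "pop2",
                            n_boot = 100, seed = r)$theta
  }, numeric(1))
  # sampling two finite subsets of one copied founder pool leaves an O(1/2Ne)
  # clone-overlap term in the Weir-Cockerham estimator
  expect_lt(abs(mean(thetas)),
            3 * sd(thetas) / sqrt(length(thetas)) + 1 / (2 * 60))
})

test_that("neutral drift is unbiased: frequency change has mean zero", {
  # sites within a chromosome share drift through linkage, so the unit of
  # independence is the chromosome: t-test on per-chromosome mean changes
  ds <- simulate_dataset(sim_config(seed = 301, n_populations = 1, ne = 150,
                                    generations = 3, n_chromosomes = 50,
                                    n_snps_per_chrom = 200, sample_sizes = 150))
  p_now <- colMeans(ds$genotypes$dosage) / 2
  deltas <- vapply(ds$truth$ancestral_freq, function(p0)
    mean(p_now[names(p0)] - p0), numeric(1))
  tt <- t.test(deltas)
  expect_gt(tt$p.value, 0.01)
})

test_that("a conditioned sweep fixes in the target population within its window", {
  sw <- list(population = 2, chrom = 1, pos = 5e6, s = 0.1,
             start_generation = 1, initial_freq = 0.3,
             condition_on_fixation = TRUE, fix_by_generation = 60)
  cfg <- sim_config(seed = 77, n_populations = 2, ne = 60, generations = 60,
                    n_chromosomes = 1, n_snps_per_chrom = 200,
                    chrom_length_bp = 1e7, sample_sizes = 20, sweep = sw,
                    max_retries = 100)
  ds <- suppressMessages(simulate_dataset(cfg))
  expect_true(ds$truth$sweep$fixed)
  expect_lte(ds$truth$sweep$fix_generation, 60)
  j <- match(ds$truth$sweep$snp_id, ds$genotypes$variants$snp_id)
  p2 <- mean(ds$genotypes$dosage[ds$genotypes$samples$population == "pop2", j]) / 2
  expect_equal(p2, 1)
})

test_that("planted relatives have the expected genomic sharing", {
  ds <- simulate_dataset(sim_config(seed = 88, n_populations = 1, ne = 60,
                                    generations = 5, n_chromosomes = 4,
                                    n_snps_per_chrom = 500, sample_sizes = 15))
  ds2 <- plant_relatives(ds, data.frame(
    new_id = c("sib1", "sib2", "kid"),
    type = c("offspring", "offspring", "offspring"),
    parent1 = c("pop1_1", "pop1_1", "sib1"),
    parent2 = c("pop1_2", "pop1_2", "sib2")), seed = 7)
  expect_error(plant_relatives(ds, data.frame(new_id = "x", type = "offspring",
                                              parent1 = "nope", parent2 = "pop1_1")),
               "unknown parent")
  # consistency of added samples
  for (h in ds2$haplotypes) {
    hd <- haplotype_dosage(h)
    expect_identical(unname(hd[c("sib1", "sib2", "kid"), ]),
                     unname(ds2$genotypes$dosage[c("sib1", "sib2", "kid"),
                                                 colnames(hd)]))
  }
  expect_equal(nrow(ds2$truth$pedigree), 3L)
})

test_that("PLINK export round-trips and is byte-deterministic", {
  cfg <- sim_config(seed = 31, n_populations = 2, ne = 30, generations = 6,
                    n_chromosomes = 2, n_snps_per_chrom = 50, sample_sizes = 8)
  ds <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_dataset(ds, d1, "plink_text")
  export_dataset(ds, d2, "plink_text")
  expect_identical(unname(tools::md5sum(file.path(d1, "genotypes.ped"))),
                   unname(tools::md5sum(file.path(d2, "genotypes.ped"))))
  g2 <- read_plink_text(file.path(d1, "genotypes.ped"),
                        file.path(d1, "genotypes.map"))
  expect_identical(unname(g2$dosage), unname(ds$genotypes$dosage))
  expect_true(file.exists(file.path(d1, "truth.json")))
  tr <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(tr$config$seed, 31)
})

test_that("phased VCF export round-trips haplotypes", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- sim_config(seed = 32, n_populations = 1, ne = 20, generations = 4,
                    n_chromosomes = 2, n_snps_per_chrom = 30, sample_sizes = 6)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  export_dataset(ds, dir, "vcf_phased")
  h <- read_vcf(file.path(dir, "genotypes.vcf"), require_phased = TRUE)
  for (ch in names(ds$haplotypes)) {
    expect_identical(unname(h[[ch]]$haplos), unname(ds$haplotypes[[ch]]$haplos))
    expect_identical(h[[ch]]$variants$pos, ds$haplotypes[[ch]]$variants$pos)
  }
  # phased export refuses missing genotypes
  dsm <- simulate_dataset(sim_config(seed = 33, n_populations = 1, ne = 20,
                                     generations = 2, n_chromosomes = 1,
                                     n_snps_per_chrom = 20, sample_sizes = 5,
                                     missing_rate = 0.2))
  expect_error(export_dataset(dsm, dir, "vcf_phased"), "complete genotypes")
})

test_that("simulated LD decays with physical distance", {
  ds <- simulate_dataset(sim_config(seed = 44, n_populations = 1, ne = 80,
                                    generations = 40, n_chromosomes = 2,
                                    n_snps_per_chrom = 300, chrom_length_bp = 2e7,
                                    sample_sizes = 40))
  cv <- ld_decay_curve(ds$genotypes, max_dist_bp = 3e6, bin_width_bp = 3e5)
  ok <- !is.na(cv$mean_r2)
  expect_lt(cor(seq_len(sum(ok)), cv$mean_r2[ok], method = "spearman"), 0)
})
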