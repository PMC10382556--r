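# genotype containers, PLINK text and VCF parsing, dataset merging

test_that("PED/MAP reading maps alleles to dosages and handles missing calls", {
  dir <- withr::local_tempdir()
  fx <- write_ped_map(
    dir,
    fam = list(c("popA", "s1", 0, 0, 0, -9), c("popA", "s2", 0, 0, 0, -9)),
    geno = list(c("A", "A", "A", "C", "0", "0"),
                c("A", "C", "C", "C", "A", "A")),
    map = cbind("1", c("rs1", "rs2", "rs3"), "0", c(100, 200, 300)))
  g <- read_plink_text(fx$ped, fx$map)
  expect_equal(dim(g$dosage), c(2L, 3L))
  # rs1: alleles A/C, s1 = AA -> 0, s2 = AC -> 1
  expect_equal(unname(g$dosage[, "rs1"]), c(0L, 1L))
  expect_equal(unname(g$dosage[, "rs2"]), c(1L, 2L))
  # "0 0" is a missing call, never dosage 0
  expect_true(is.na(g$dosage["s1", "rs3"]))
  expect_equal(g$dosage["s2", "rs3"], 0L)
  expect_equal(g$samples$population, c("popA", "popA"))
})

test_that("unsorted MAP positions are sorted with columns permuted consistently", {
  dir <- withr::local_tempdir()
  fx <- write_ped_map(
    dir,
    fam = list(c("p", "s1", 0, 0, 0, -9)),
    geno = list(c("A", "C", "C", "C", "A", "A")),
    map = cbind("1", c("rs_b", "rs_c", "rs_a"), "0", c(500, 900, 100)))
  g <- read_plink_text(fx$ped, fx$map)
  expect_equal(g$variants$snp_id, c("rs_a", "rs_b", "rs_c"))
  expect_equal(g$variants$pos, c(100L, 500L, 900L))
  # hand-sorted expectation: rs_a was the 3rd genotype (AA -> 0),
  # rs_b the 1st (AC -> 1), rs_c the 2nd (CC -> 2)
  expect_equal(unname(g$dosage[1, ]), c(0L, 1L, 2L))
})

test_that("ragged PED rows and >2 alleles are rejected with informative errors", {
  dir <- withr::local_tempdir()
  fx <- write_ped_map(dir,
                      fam = list(c("p", "s1", 0, 0, 0, -9)),
                      geno = list(c("A", "C")),
                      map = cbind("1", c("rs1", "rs2"), "0", c(1, 2)))
  expect_error(read_plink_text(fx$ped, fx$map), "ragged PED row at line 1")
  fx2 <- write_ped_map(dir,
                       fam = list(c("p", "s1", 0, 0, 0, -9),
                                  c("p", "s2", 0, 0, 0, -9)),
                       geno = list(c("A", "C"), c("G", "T")),
                       map = cbind("1", "rs1", "0", 1))
  expect_error(read_plink_text(fx2$ped, fx2$map), ">2 distinct alleles")
})

test_that("PLINK text round-trip preserves dosage, ids and positions exactly", {
  ds <- simulate_dataset(sim_config(seed = 3, n_populations = 2, ne = 30,
                                    generations = 5, n_chromosomes = 2,
                                    n_snps_per_chrom = 40, sample_sizes = 8,
                                    missing_rate = 0.05))
  dir <- withr::local_tempdir()
  write_plink_text(ds$genotypes, file.path(dir, "rt"))
  g2 <- read_plink_text(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_identical(unname(g2$dosage), unname(ds$genotypes$dosage))
  expect_identical(g2$variants$snp_id, ds$genotypes$variants$snp_id)
  expect_identical(g2$variants$pos, ds$genotypes$variants$pos)
  expect_identical(g2$samples$sample_id, ds$genotypes$samples$sample_id)
})

test_that("VCF genotypes map GT to dosage and ./. to missing", {
  skip_if_not_installed("VariantAnnotation")
  dir <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(dir, "t.vcf"), c("s1", "s2"), list(
    c("chr1", 100, "v1", "A", "G", ".", "PASS", ".", "GT", "0/1", "1/1"),
    c("chr1", 200, "v2", "C", "T", ".", "PASS", ".", "GT", "./.", "0/0"),
    c("chr1", 300, "v3", "C", "T,G", ".", "PASS", ".", "GT", "0/0", "0/0")))
  g <- suppressMessages(read_vcf(vcf))
  expect_equal(ncol(g$dosage), 2L)       # multi-allelic record skipped
  expect_equal(unname(g$dosage[, "v1"]), c(1L, 2L))
  expect_true(is.na(g$dosage["s1", "v2"]))
  expect_equal(g$dosage["s2", "v2"], 0L)
})

test_that("phased VCF yields haplotypes consistent with dosages", {
  skip_if_not_installed("VariantAnnotation")
  dir <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(dir, "p.vcf"), c("s1", "s2"), list(
    c("chr1", 100, "v1", "A", "G", ".", "PASS", ".", "GT", "0|1", "1|1"),
    c("chr1", 200, "v2", "C", "T", ".", "PASS", ".", "GT", "1|0", "0|0")))
  h <- read_vcf(vcf, require_phased = TRUE)
  expect_named(h, "chr1")
  expect_equal(nrow(h$chr1$haplos), 4L)
  hd <- haplotype_dosage(h$chr1)
  expect_equal(unname(hd["s1", ]), c(1L, 1L))
  expect_equal(unname(hd["s2", ]), c(2L, 0L))
  # unphased separator rejected when phase is required
  vcf2 <- write_toy_vcf(file.path(dir, "u.vcf"), "s1", list(
    c("chr1", 100, "v1", "A", "G", ".", "PASS", ".", "GT", "0/1")))
  expect_error(read_vcf(vcf2, require_phased = TRUE), "unphased")
})

test_that("merge keeps the locus intersection and harmonizes orientation", {
  gA <- toy_genotypes(rbind(c(0L, 1L, 2L, 1L)), chrom = rep("chr1", 4),
                      pos = c(1e5, 2e5, 3e5, 4e5))
  gA$variants$snp_id <- c("a", "b", "c", "d")
  gA$variants$allele_a <- c("A", "A", "A", "A")
  gA$variants$allele_b <- c("C", "G", "C", "T")   # d is A/T: ambiguous
  gB <- toy_genotypes(rbind(c(2L, 0L, 1L)), populations = "popB",
                      chrom = rep("chr1", 3), pos = c(2e5, 3e5, 4e5))
  gB$samples$sample_id <- "t1"
  gB$variants$snp_id <- c("b", "c", "d")
  gB$variants$allele_a <- c("G", "A", "A")        # b swapped vs gA
  gB$variants$allele_b <- c("A", "C", "T")
  m <- merge_datasets(list(gA, gB), verbose = FALSE)
  expect_setequal(m$variants$snp_id, c("b", "c"))  # a absent in B, d ambiguous
  expect_equal(m$dosage["t1", "b"], 2L - 2L)       # flipped orientation
  expect_equal(m$dosage["t1", "c"], 0L)
  expect_equal(m$dosage["s1", "b"], 1L)
})

test_that("merge locus sets behave associatively", {
  mk <- function(ids, pos0) {
    g <- toy_genotypes(rbind(rep(1L, length(ids))), chrom = rep("chr1", length(ids)),
                       pos = pos0 + seq_along(ids) * 1000L)
    g$variants$snp_id <- ids
    g
  }
  gA <- mk(c("a", "b", "c"), 0L)
  gB <- mk(c("b", "c", "d"), 0L); gB$samples$sample_id <- "x1"
  gC <- mk(c("b", "c", "e"), 0L); gC$samples$sample_id <- "y1"
  m3 <- merge_datasets(list(gA, gB, gC), verbose = FALSE)
  expect_setequal(m3$variants$snp_id,
                  Reduce(intersect, list(c("a", "b", "c"), c("b", "c", "d"),
                                         c("b", "c", "e"))))
})

test_that("haplotype/genotype consistency invariant holds for simulated data", {
  ds <- simulate_dataset(sim_config(seed = 9, n_populations = 2, ne = 25,
                                    generations = 4, n_chromosomes = 2,
                                    n_snps_per_chrom = 30, sample_sizes = 6))
  for (h in ds$haplotypes) {
    hd <- haplotype_dosage(h)
    expect_identical(unname(hd[rownames(ds$genotypes$dosage), ]),
                     unname(ds$genotypes$dosage[, colnames(hd)]))
  }
})
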