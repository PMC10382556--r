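# Shared fixture builders. Everything is generated in code; no binary files.

# tiny genotypes object from a dosage matrix (chrom defaults to one
# chromosome, positions 1e5 apart)
toy_genotypes <- function(dosage, populations = NULL, chrom = NULL,
                          pos = NULL, alleles = c("A", "C")) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  variants <- data.frame(
    snp_id = paste0("snp", seq_len(m)),
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% (seq_len(m) * 100000L),
    allele_a = alleles[1], allele_b = alleles[2],
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    population = populations %||% rep("popA", n),
    stringsAsFactors = FALSE)
  new_genotypes(dosage, variants, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a small PED/MAP pair; geno is a list of rows, each a character
# vector of 2M allele fields
write_ped_map <- function(dir, fam, geno, map) {
  ped <- file.path(dir, "toy.ped")
  mapf <- file.path(dir, "toy.map")
  writeLines(vapply(seq_along(geno), function(i)
    paste(c(fam[[i]], geno[[i]]), collapse = " "), character(1)), ped)
  writeLines(apply(map, 1L, paste, collapse = "\t"), mapf)
  list(ped = ped, map = mapf)
}

# small VCF writer for fixtures
write_toy_vcf <- function(path, samples, records) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(records, function(r) paste(r, collapse = "\t"), character(1))
  ), path)
  path
}

# independent exact-HWE oracle: full enumeration of the conditional
# distribution of heterozygote counts given allele counts
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  w <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2; bb <- (n_b - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2))
  }, numeric(1))
  p <- w / sum(w)
  sum(p[p <= p[match(n_ab, hets)] * (1 + 1e-12)])
}

# planted-ROH fixture: heterozygous flanks around 30 consecutive homozygous
# SNPs spanning ~600 kbps at ~20 kbps spacing, satisfying every ROH filter
planted_run_genotypes <- function(gap_at = NULL, gap_bp = 1.2e6) {
  spacing <- 20000L
  geno <- c(rep(1L, 40), rep(c(0L, 2L), length.out = 30), rep(1L, 40))
  pos <- cumsum(rep(spacing, length(geno)))
  pos[41:70] <- pos[41] + seq(0L, by = 20690L, length.out = 30)
  pos[71:110] <- pos[70] + seq(20000L, by = 20000L, length.out = 40)
  if (!is.null(gap_at)) pos[gap_at:length(pos)] <- pos[gap_at:length(pos)] + gap_bp
  list(geno = geno, pos = as.integer(pos))
}

# brute-force scanline ROH oracle used against detect_roh on fixtures:
# independently re-derives window homozygosity, the SNP vote, and the
# segment filters
roh_oracle <- function(geno, pos, params) {
  m <- length(geno)
  w <- params$window_size_snps
  if (m < w) return(NULL)
  win_hom <- vapply(seq_len(m - w + 1L), function(s) {
    win <- geno[s:(s + w - 1L)]
    sum(win == 1L, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(win)) <= params$max_miss_per_window
  }, logical(1))
  in_run <- vapply(seq_len(m), function(j) {
    ws <- max(1L, j - w + 1L):min(m - w + 1L, j)
    mean(win_hom[ws]) >= params$overlap_threshold
  }, logical(1))
  segs <- list()
  j <- 1L
  while (j <= m) {
    if (!in_run[j]) { j <- j + 1L; next }
    k <- j
    while (k < m && in_run[k + 1L]) k <- k + 1L
    idx <- j:k
    brk <- which(diff(pos[idx]) > params$max_gap_bp)
    pieces <- split(idx, c(0, cumsum(seq_along(idx)[-1] %in% (brk + 1L))))
    for (pc in pieces) {
      len <- pos[pc[length(pc)]] - pos[pc[1]] + 1L
      if (length(pc) >= params$min_snp && len >= params$min_length_bp &&
          len / length(pc) <= params$min_density_bp_per_snp)
        segs[[length(segs) + 1L]] <- c(start = pos[pc[1]],
                                       end = pos[pc[length(pc)]],
                                       n = length(pc))
    }
    j <- k + 1L
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}
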