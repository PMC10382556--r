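# Genotype containers and text-format I/O (PLINK PED/MAP, VCF).
#
# The central container is the S3 class "genotypes": a samples x SNPs dosage
# matrix (counts of allele_b; NA = missing call) with a variant table and a
# sample table. Phased data live in the S3 class "haplotypes", one object per
# chromosome. Coordinates are 1-based inclusive throughout.

#' Construct a genotype matrix object
#'
#' Bundles a dosage matrix with its variant and sample tables and validates
#' the invariants every downstream analysis relies on.
#'
#' @param dosage integer matrix (samples x SNPs) with values 0, 1, 2 counting
#'   copies of `allele_b`, or `NA` for a missing call.
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`. Rows are sorted by (chrom, pos) on construction.
#' @param samples data.frame with columns `sample_id`, `population`.
#' @return An object of class `genotypes` with elements `dosage`, `variants`,
#'   `samples`.
#' @export
new_genotypes <- function(dosage, variants, samples) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need_v %in% names(variants)))
    ps_stop("variants must have columns: %s", paste(need_v, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(samples)))
    ps_stop("samples must have columns sample_id, population")
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants))
    ps_stop("dosage dimensions (%d x %d) do not match samples (%d) / variants (%d)",
            nrow(dosage), ncol(dosage), nrow(samples), nrow(variants))
  if (anyDuplicated(variants$snp_id))
    ps_stop("duplicated snp_id in variant table")
  if (anyDuplicated(samples$sample_id))
    ps_stop("duplicated sample_id in sample table")
  if (any(variants$allele_a == variants$allele_b))
    ps_stop("allele_a equals allele_b at %d loci",
            sum(variants$allele_a == variants$allele_b))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    ps_stop("dosage values must be 0, 1, 2 or NA")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  dimnames(dosage) <- list(samples$sample_id, variants$snp_id)
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("<genotypes> %d samples x %d SNPs, %d population(s), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$samples$population)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosage)

#' Subset a genotypes object by samples and/or SNPs
#'
#' @param g a `genotypes` object.
#' @param samples logical/integer/character index into samples (optional).
#' @param snps logical/integer/character index into SNPs (optional).
#' @return A `genotypes` object.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotypes"))
  si <- if (is.null(samples)) seq_len(nrow(g$dosage)) else samples
  if (is.character(si)) si <- match(si, g$samples$sample_id)
  vi <- if (is.null(snps)) seq_len(ncol(g$dosage)) else snps
  if (is.character(vi)) vi <- match(vi, g$variants$snp_id)
  new_genotypes(g$dosage[si, vi, drop = FALSE],
                g$variants[vi, , drop = FALSE],
                g$samples[si, , drop = FALSE])
}

#' Construct a phased haplotype set for one chromosome
#'
#' @param haplos binary matrix (2N x M); rows i, i+1 for odd i belong to one
#'   sample. Entry 1 means the haplotype carries `allele_b`.
#' @param variants variant table restricted to a single chromosome.
#' @param sample_of_haplotype character vector (length 2N) mapping each
#'   haplotype row to its sample_id; each sample must appear exactly twice.
#' @return An object of class `haplotypes`.
#' @export
new_haplotypes <- function(haplos, variants, sample_of_haplotype) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  haplos <- as.matrix(haplos)
  storage.mode(haplos) <- "integer"
  if (length(unique(variants$chrom)) > 1L)
    ps_stop("a haplotypes object spans a single chromosome")
  if (nrow(haplos) != length(sample_of_haplotype))
    ps_stop("sample_of_haplotype length must equal nrow(haplos)")
  tab <- table(sample_of_haplotype)
  if (any(tab != 2L))
    ps_stop("every sample must contribute exactly 2 haplotypes")
  if (!all(haplos %in% c(0L, 1L)))
    ps_stop("haplotypes must be binary (0/1) with no missing values")
  ord <- order(variants$pos)
  structure(list(haplos = haplos[, ord, drop = FALSE],
                 variants = variants[ord, , drop = FALSE],
                 sample_of_haplotype = as.character(sample_of_haplotype)),
            class = "haplotypes")
}

#' @export
print.haplotypes <- function(x, ...) {
  cat(sprintf("<haplotypes> chrom %s: %d haplotypes x %d SNPs\n",
              x$variants$chrom[1], nrow(x$haplos), ncol(x$haplos)))
  invisible(x)
}

#' Dosage implied by a haplotype set
#'
#' Sums the two haplotypes of each sample; used to check phase/genotype
#' consistency.
#'
#' @param h a `haplotypes` object.
#' @return integer matrix (N x M) with sample_id rownames.
#' @export
haplotype_dosage <- function(h) {
  ids <- unique(h$sample_of_haplotype)
  d <- vapply(ids, function(s) {
    colSums(h$haplos[h$sample_of_haplotype == s, , drop = FALSE])
  }, numeric(ncol(h$haplos)))
  d <- t(d)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(ids, h$variants$snp_id)
  d
}

# ---------------------------------------------------------------------------
# PLINK text

#' Read PLINK text (PED/MAP) genotypes
#'
#' @param ped_path path to the PED file (6 leading columns, then two allele
#'   columns per SNP; "0 0" encodes a missing call).
#' @param map_path path to the 4-column MAP file (chrom, snp_id, cM, pos).
#' @return A `genotypes` object; dosage counts copies of `allele_b`, where
#'   `allele_a`/`allele_b` are the first/second distinct alleles observed at
#'   the locus (alphabetical when both appear equally).
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) ps_stop("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) ps_stop("MAP file not found: %s", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric", "integer"))
  if (ncol(map) != 4L) ps_stop("MAP must have 4 columns, found %d", ncol(map))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf != 6L + 2L * m)
  if (length(bad))
    ps_stop("ragged PED row at line %d: %d fields, expected %d",
            bad[1], nf[bad[1]], 6L + 2L * m)
  n <- length(toks)
  fam <- t(vapply(toks, function(x) x[1:6], character(6)))
  a1 <- t(vapply(toks, function(x) x[6L + 2L * seq_len(m) - 1L], character(m)))
  a2 <- t(vapply(toks, function(x) x[6L + 2L * seq_len(m)], character(m)))
  dim(a1) <- dim(a2) <- c(n, m)
  dosage <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    al <- sort(unique(obs))
    if (length(al) > 2L)
      ps_stop("locus %s has >2 distinct alleles: %s",
              map[[2]][j], paste(al, collapse = ","))
    if (length(al) == 0L) al <- c("A", "B")      # fully missing locus
    # monomorphic locus: pad with a placeholder allele, keep alphabetical
    # order so round-trips of A/C-coded data preserve dosage
    if (length(al) == 1L)
      al <- sort(c(al, if (al == "A") "B" else "A"))
    allele_a[j] <- al[1]; allele_b[j] <- al[2]
    d <- (x1 == al[2]) + (x2 == al[2])
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  variants <- data.frame(snp_id = map[[2]], chrom = map[[1]], pos = map[[4]],
                         allele_a = allele_a, allele_b = allele_b,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam[, 2], population = fam[, 1],
                        stringsAsFactors = FALSE)
  new_genotypes(dosage, variants, samples)
}

#' Write PLINK text (PED/MAP) genotypes
#'
#' Inverse of [read_plink_text()]: `population` becomes the family id and
#' missing dosages are written as "0 0". Output column order is deterministic.
#'
#' @param g a `genotypes` object.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The two file paths, invisibly.
#' @export
write_plink_text <- function(g, prefix) {
  stopifnot(inherits(g, "genotypes"))
  v <- g$variants
  map <- data.frame(v$chrom, v$snp_id, 0, v$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  code <- function(d, a, b) {
    # d scalar-vectorized over samples for one SNP
    out1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, b, a))
    out2 <- ifelse(is.na(d), "0", ifelse(d == 2L, b, a))
    paste(out1, out2)
  }
  geno_cols <- vapply(seq_len(m), function(j)
    code(g$dosage[, j], v$allele_a[j], v$allele_b[j]), character(n))
  dim(geno_cols) <- c(n, m)
  lead <- cbind(g$samples$population, g$samples$sample_id, "0", "0", "0", "-9")
  lines <- apply(cbind(lead, geno_cols), 1L, paste, collapse = " ")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

# ---------------------------------------------------------------------------
# VCF

#' Read a VCF into genotypes or phased haplotypes
#'
#' Only biallelic SNP records are used; other records are skipped with a
#' message. Parsing is delegated to VariantAnnotation; this function maps GT
#' strings to dosages (and, when `require_phased`, to per-chromosome
#' haplotype sets).
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param require_phased if TRUE, all GT fields must use the `|` separator and
#'   the result is a list of `haplotypes` objects (one per chromosome);
#'   otherwise a `genotypes` object is returned.
#' @param population population label(s) for the samples (recycled).
#' @return A `genotypes` object, or a named list of `haplotypes`.
#' @export
read_vcf <- function(vcf_path, require_phased = FALSE, population = "pop1") {
  if (!file.exists(vcf_path)) ps_stop("VCF not found: %s", vcf_path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    ps_stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1L] <- vapply(which(n_alt >= 1L), function(i)
    as.character(altl[[i]][1]), character(1))
  keep <- n_alt == 1L & nchar(ref) == 1L & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0L)
    message(sprintf("read_vcf: skipped %d non-biallelic/non-SNP record(s)", n_skip))
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  ids <- rownames(vcf)[keep]
  if (is.null(ids) || anyDuplicated(ids))
    ids <- paste0(chrom, "_", pos)
  variants <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                         allele_a = ref[keep], allele_b = alt1[keep],
                         stringsAsFactors = FALSE)
  samp_ids <- colnames(gt)
  samples <- data.frame(sample_id = samp_ids,
                        population = rep_len(population, length(samp_ids)),
                        stringsAsFactors = FALSE)
  if (require_phased) {
    unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow(gt), ncol(gt))
    if (any(unphased)) {
      idx <- which(unphased, arr.ind = TRUE)
      ps_stop("require_phased: %d unphased GT field(s), e.g. variant %s sample %s",
              sum(unphased), variants$snp_id[idx[1, 1]], samp_ids[idx[1, 2]])
    }
    if (any(gt %in% c(".|.", ".", ".|0", "0|.")))
      ps_stop("require_phased: missing genotypes are not representable as haplotypes")
    h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
    h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
    out <- list()
    for (ch in unique(variants$chrom)) {
      vi <- which(variants$chrom == ch)
      haps <- matrix(0L, 2L * length(samp_ids), length(vi))
      haps[seq(1, nrow(haps), 2), ] <- t(h1[vi, , drop = FALSE])
      haps[seq(2, nrow(haps), 2), ] <- t(h2[vi, , drop = FALSE])
      out[[ch]] <- new_haplotypes(haps, variants[vi, , drop = FALSE],
                                  rep(samp_ids, each = 2L))
    }
    return(out)
  }
  first <- substr(gt, 1, 1)
  second <- substr(gt, 3, 3)
  d <- suppressWarnings(as.integer(first) + as.integer(second))
  dosage <- t(matrix(d, nrow(gt), ncol(gt)))
  new_genotypes(dosage, variants, samples)
}

#' Write phased haplotypes as a VCF
#'
#' @param haps_list named list of `haplotypes` objects (one per chromosome),
#'   all with identical sample sets.
#' @param path output path (plain text VCF v4.2).
#' @return `path`, invisibly.
#' @export
write_vcf_phased <- function(haps_list, path) {
  if (inherits(haps_list, "haplotypes")) haps_list <- list(haps_list)
  ids <- unique(haps_list[[1]]$sample_of_haplotype)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popsweep",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (h in haps_list) {
    stopifnot(identical(unique(h$sample_of_haplotype), ids))
    v <- h$variants
    i1 <- match(ids, h$sample_of_haplotype)                 # first haplotype row
    i2 <- nrow(h$haplos) + 1L - match(ids, rev(h$sample_of_haplotype))
    gt1 <- h$haplos[i1, , drop = FALSE]
    gt2 <- h$haplos[i2, , drop = FALSE]
    for (j in seq_len(nrow(v))) {
      gts <- paste0(gt1[, j], "|", gt2[, j])
      writeLines(paste(c(v$chrom[j], v$pos[j], v$snp_id[j], v$allele_a[j],
                         v$allele_b[j], ".", "PASS", ".", "GT", gts),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Merging

#' Merge genotype datasets on their locus intersection
#'
#' Keeps SNPs shared (by snp_id) across all datasets, harmonizes alleles to
#' the first dataset's orientation (flipping dosage d -> 2 - d where the
#' allele pair is swapped), and drops strand-ambiguous A/T and C/G loci as
#' well as loci whose allele sets cannot be reconciled by a swap.
#'
#' @param datasets list of two or more `genotypes` objects with disjoint
#'   sample ids.
#' @param verbose log counts of dropped loci.
#' @return A `genotypes` object containing all samples and the harmonized
#'   locus intersection.
#' @export
merge_datasets <- function(datasets, verbose = TRUE) {
  if (length(datasets) < 2L) ps_stop("merge_datasets needs >= 2 datasets")
  ids <- unlist(lapply(datasets, function(d) d$samples$sample_id))
  if (anyDuplicated(ids)) ps_stop("duplicated sample_id across datasets")
  shared <- Reduce(intersect, lapply(datasets, function(d) d$variants$snp_id))
  ref <- datasets[[1]]
  vref <- ref$variants[match(shared, ref$variants$snp_id), , drop = FALSE]
  ambiguous <- (vref$allele_a == "A" & vref$allele_b == "T") |
    (vref$allele_a == "T" & vref$allele_b == "A") |
    (vref$allele_a == "C" & vref$allele_b == "G") |
    (vref$allele_a == "G" & vref$allele_b == "C")
  keep <- shared[!ambiguous]
  n_amb <- sum(ambiguous)
  vref <- vref[!ambiguous, , drop = FALSE]
  irreconcilable <- rep(FALSE, length(keep))
  dos_list <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    idx <- match(keep, d$variants$snp_id)
    vv <- d$variants[idx, , drop = FALSE]
    dd <- d$dosage[, idx, drop = FALSE]
    same <- vv$allele_a == vref$allele_a & vv$allele_b == vref$allele_b
    swapped <- vv$allele_a == vref$allele_b & vv$allele_b == vref$allele_a
    irreconcilable <- irreconcilable | !(same | swapped)
    if (any(swapped)) dd[, swapped] <- 2L - dd[, swapped, drop = FALSE]
    dos_list[[k]] <- dd
  }
  n_irr <- sum(irreconcilable)
  if (n_irr > 0L) {
    keep_f <- !irreconcilable
    vref <- vref[keep_f, , drop = FALSE]
    dos_list <- lapply(dos_list, function(x) x[, keep_f, drop = FALSE])
  }
  ps_msg(verbose, "merge_datasets: %d shared loci, dropped %d strand-ambiguous and %d irreconcilable",
         length(shared), n_amb, n_irr)
  samples <- do.call(rbind, lapply(datasets, function(d) d$samples))
  new_genotypes(do.call(rbind, dos_list), vref, samples)
}
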