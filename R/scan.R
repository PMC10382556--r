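# The pairwise selection scan: per-SNP Weir-Cockerham FST, FLK with a
# kinship from the pairwise Reynolds-distance tree, xp-EHH from phased
# haplotypes, combined by DCMS with robust correlation weighting, robust
# normal calibration and BH false-discovery control.

#' Configuration for a pairwise selection scan
#'
#' @param seed master seed (MCD subsampling).
#' @param ehh_min EHH truncation level (default 0.05).
#' @param max_gap_bp maximum inter-marker gap inside an EHH integration
#'   span (default 2e5).
#' @param mcd_alpha,mcd_subsample FAST-MCD parameters (defaults 0.75, 30000).
#' @param q_threshold BH significance level (default 0.05).
#' @return list of validated settings.
#' @export
scan_config <- function(seed = 1L, ehh_min = 0.05, max_gap_bp = 2e5,
                        mcd_alpha = 0.75, mcd_subsample = 30000L,
                        q_threshold = 0.05) {
  list(seed = as.integer(seed), ehh_min = ehh_min, max_gap_bp = max_gap_bp,
       mcd_alpha = mcd_alpha, mcd_subsample = as.integer(mcd_subsample),
       q_threshold = q_threshold)
}

#' @keywords internal
#' @noRd
subset_haplotypes_pop <- function(h, sample_ids) {
  keep <- h$sample_of_haplotype %in% sample_ids
  new_haplotypes(h$haplos[keep, , drop = FALSE], h$variants,
                 h$sample_of_haplotype[keep])
}

#' Run one pairwise selection scan
#'
#' Composes the full statistic stack for two populations: per-SNP FST and
#' Z(FST); FLK with the 2x2 kinship derived from the pairwise Reynolds
#' distance (two half-distance branches); xp-EHH with `popA` as numerator
#' (positive scores: longer haplotypes, i.e. a sweep, in popA); fractional
#' right-tailed p-values; MCD correlation of the three statistics; DCMS;
#' robust-normal calibration; BH q-values. SNPs undefined in any statistic
#' are excluded from the composite and counted. The reverse orientation
#' (popB numerator) is reported in the `*_rev` columns.
#'
#' @param g a `genotypes` object containing both populations.
#' @param haplotypes named list of per-chromosome `haplotypes` objects
#'   covering the samples of both populations (same variant map as `g`).
#' @param popA,popB population labels; popA is the focal population of the
#'   primary right tail.
#' @param config from [scan_config()].
#' @return data.frame (one row per SNP kept in `g` for the two populations)
#'   with columns snp_id, chrom, pos, fst_theta, zfst, flk_stat, flk_p,
#'   xpehh_raw, xpehh_z, frac_p_fst, frac_p_flk, frac_p_xpehh, dcms,
#'   dcms_p, q_value, significant, dcms_rev, dcms_p_rev, q_value_rev;
#'   attributes `kinship`, `correlation`, `n_excluded_dcms`.
#' @export
run_pairwise_scan <- function(g, haplotypes, popA, popB,
                              config = scan_config()) {
  stopifnot(inherits(g, "genotypes"))
  sel <- g$samples$population %in% c(popA, popB)
  g2 <- subset_genotypes(g, samples = which(sel))
  # drop SNPs without a defined frequency in each population or monomorphic
  # across the pair (no information for any statistic)
  freqs <- allele_frequencies(g2)
  pa <- freqs$p[popA, ]; pb <- freqs$p[popB, ]
  pool <- colMeans(g2$dosage, na.rm = TRUE) / 2
  keep <- !is.na(pa) & !is.na(pb) & pool > 0 & pool < 1
  g2 <- subset_genotypes(g2, snps = which(keep))
  v <- g2$variants
  freqs <- allele_frequencies(g2)

  fst <- per_snp_wc_fst(g2, popA, popB)
  zf <- zfst(fst)

  dmat <- distance_matrix(freqs, "reynolds")[c(popA, popB), c(popA, popB)]
  tree <- build_population_tree(dmat)
  F <- kinship_from_tree(tree)
  # indistinguishable populations give a zero-length tree; floor the drift
  # so the FLK quadratic form stays defined (ranks are unaffected)
  diag(F) <- pmax(diag(F), 1e-6)
  flk <- flk_test(freqs$p[c(popA, popB), , drop = FALSE], F)

  idsA <- g2$samples$sample_id[g2$samples$population == popA]
  idsB <- g2$samples$sample_id[g2$samples$population == popB]
  xp_raw <- rep(NA_real_, nrow(v)); names(xp_raw) <- v$snp_id
  for (h in haplotypes) {
    # cores: SNPs kept for this pair; the EHH walk uses the full phased map
    # so that dropped (e.g. hitchhiked-to-fixation) markers do not create
    # artificial gaps
    common <- intersect(h$variants$snp_id, v$snp_id)
    if (length(common) == 0L) next
    ha <- subset_haplotypes_pop(h, idsA)
    hb <- subset_haplotypes_pop(h, idsB)
    xp_raw[common] <- xpehh(ha, hb, config$ehh_min, config$max_gap_bp,
                            cores = match(common, h$variants$snp_id))[common]
  }
  xp_z <- if (sum(!is.na(xp_raw)) >= 2L) standardize_xpehh(xp_raw) else xp_raw

  stats3 <- cbind(fst = fst, flk = flk$stat, xpehh = xp_z)
  complete <- stats::complete.cases(stats3)
  n_excl <- sum(!complete)

  frac <- matrix(NA_real_, nrow(v), 3,
                 dimnames = list(v$snp_id, c("fst", "flk", "xpehh")))
  frac_rev <- frac
  if (sum(complete) >= 10L) {
    frac[complete, "fst"] <- fractional_rank_pvalues(fst[complete])
    frac[complete, "flk"] <- fractional_rank_pvalues(flk$stat[complete])
    frac[complete, "xpehh"] <- fractional_rank_pvalues(xp_z[complete])
    frac_rev[, c("fst", "flk")] <- frac[, c("fst", "flk")]
    frac_rev[complete, "xpehh"] <- fractional_rank_pvalues(-xp_z[complete])
    corr <- mcd_covariance(stats3[complete, , drop = FALSE],
                           alpha = config$mcd_alpha,
                           subsample = config$mcd_subsample,
                           seed = config$seed)
    d_fwd <- rep(NA_real_, nrow(v))
    d_rev <- rep(NA_real_, nrow(v))
    d_fwd[complete] <- dcms(frac[complete, , drop = FALSE], corr)
    d_rev[complete] <- dcms(frac_rev[complete, , drop = FALSE], corr)
    cal_f <- calibrate_dcms(d_fwd)
    cal_r <- calibrate_dcms(d_rev)
    bh_f <- bh_fdr(cal_f$p, config$q_threshold)
    bh_r <- bh_fdr(cal_r$p, config$q_threshold)
  } else {
    ps_stop("run_pairwise_scan: fewer than 10 SNPs defined in all statistics")
  }

  out <- data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
                    fst_theta = unname(fst), zfst = unname(zf),
                    flk_stat = flk$stat, flk_p = flk$p_value,
                    xpehh_raw = unname(xp_raw), xpehh_z = unname(xp_z),
                    frac_p_fst = frac[, "fst"], frac_p_flk = frac[, "flk"],
                    frac_p_xpehh = frac[, "xpehh"],
                    dcms = d_fwd, dcms_p = cal_f$p, q_value = bh_f$q,
                    significant = bh_f$significant,
                    dcms_rev = d_rev, dcms_p_rev = cal_r$p,
                    q_value_rev = bh_r$q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # invariants asserted on every run
  qp <- out$q_value >= out$dcms_p - 1e-12
  stopifnot(all(qp[!is.na(qp)]))
  fr <- out$frac_p_fst
  stopifnot(all(fr[!is.na(fr)] > 0 & fr[!is.na(fr)] < 1))
  attr(out, "kinship") <- F
  attr(out, "correlation") <- corr
  attr(out, "n_excluded_dcms") <- n_excl
  attr(out, "populations") <- c(popA, popB)
  out
}
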