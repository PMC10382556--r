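# Quality-control cascade: call rate, MAF + exact HWE, IBD relatedness
# pruning, LD pruning. The stage order mirrors the merged-data QC pass:
# call-rate -> MAF/HWE -> relatedness; LD pruning produces analysis subsets.

#' @keywords internal
#' @noRd
new_qc_report <- function(step, params, n_snps_removed, n_samples_removed,
                          n_snps_out, n_samples_out, detail = NULL) {
  structure(list(step = step, params = params,
                 n_snps_removed = n_snps_removed,
                 n_samples_removed = n_samples_removed,
                 n_snps_out = n_snps_out, n_samples_out = n_samples_out,
                 detail = detail),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report:%s> removed %d SNP(s), %d sample(s); kept %d x %d\n",
              x$step, x$n_snps_removed, x$n_samples_removed,
              x$n_samples_out, x$n_snps_out))
  invisible(x)
}

#' Filter SNPs and samples by genotyping call rate
#'
#' SNPs are filtered first against `min_rate`, then samples against the
#' per-sample call rate computed on the SNP-filtered matrix.
#'
#' @param g a `genotypes` object.
#' @param min_rate minimum fraction of non-missing calls (default 0.90).
#' @return list(genotypes = filtered object, report = qc_report).
#' @export
filter_call_rate <- function(g, min_rate = 0.90) {
  stopifnot(inherits(g, "genotypes"), min_rate > 0, min_rate <= 1)
  called <- !is.na(g$dosage)
  snp_ok <- colMeans(called) >= min_rate
  g2 <- subset_genotypes(g, snps = which(snp_ok))
  smp_ok <- rowMeans(!is.na(g2$dosage)) >= min_rate
  g3 <- subset_genotypes(g2, samples = which(smp_ok))
  if (ncol(g3$dosage) == 0L || nrow(g3$dosage) == 0L)
    ps_stop("filter_call_rate: all data removed at min_rate = %g", min_rate)
  rep <- new_qc_report("call_rate", list(min_rate = min_rate),
                       sum(!snp_ok), sum(!smp_ok),
                       ncol(g3$dosage), nrow(g3$dosage))
  list(genotypes = g3, report = rep)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test on one SNP's genotype counts: with the allele counts
#' fixed, heterozygote counts of the same parity are enumerated and the
#' p-value is the total probability of configurations no more probable than
#' the observed one (no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb counts of the three genotypes.
#' @return exact p-value in (0, 1]; monomorphic input returns 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1L) ps_stop("hwe_exact_test: empty genotype counts")
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # P(n_ab = h | allele margins) proportional to 2^h / (aa! h! bb!);
  # constant factors cancel on normalization
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2; bb <- (n_b - h) / 2
    h * log(2) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(n_ab, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Per-SNP exact HWE p-values for a genotype matrix
#'
#' @param g a `genotypes` object (all samples pooled).
#' @return numeric vector of p-values, one per SNP.
#' @export
hwe_pvalues <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  d <- g$dosage
  n_aa <- colSums(d == 0L, na.rm = TRUE)
  n_ab <- colSums(d == 1L, na.rm = TRUE)
  n_bb <- colSums(d == 2L, na.rm = TRUE)
  vapply(seq_len(ncol(d)), function(j)
    hwe_exact_test(n_aa[j], n_ab[j], n_bb[j]), numeric(1))
}

#' Filter SNPs by minor allele frequency and Hardy-Weinberg equilibrium
#'
#' Removes SNPs with MAF strictly below `min_maf` (MAF computed on all
#' pooled samples, missing calls masked) or with exact-HWE p strictly below
#' `hwe_alpha`.
#'
#' @param g a `genotypes` object.
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE p-value threshold (default 1e-6).
#' @return list(genotypes, report); the report's detail counts removals by
#'   cause.
#' @export
filter_maf_hwe <- function(g, min_maf = 0.01, hwe_alpha = 1e-6) {
  stopifnot(inherits(g, "genotypes"), min_maf > 0, min_maf < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf_fail <- is.na(maf) | maf < min_maf
  hwe_p <- hwe_pvalues(g)
  hwe_fail <- hwe_p < hwe_alpha
  drop <- maf_fail | hwe_fail
  g2 <- subset_genotypes(g, snps = which(!drop))
  if (ncol(g2$dosage) == 0L)
    ps_stop("filter_maf_hwe: all SNPs removed")
  rep <- new_qc_report("maf_hwe", list(min_maf = min_maf, hwe_alpha = hwe_alpha),
                       sum(drop), 0L, ncol(g2$dosage), nrow(g2$dosage),
                       detail = list(n_maf = sum(maf_fail),
                                     n_hwe = sum(hwe_fail & !maf_fail)))
  list(genotypes = g2, report = rep)
}

#' Method-of-moments identity-by-descent estimates for all sample pairs
#'
#' Computes P(IBD = 0, 1, 2) for every pair from observed identity-by-state
#' counts and allele frequencies (estimated from all samples of `g` unless
#' supplied), bounds the probabilities into \[0, 1\], renormalizes, and
#' reports PI_HAT = P(IBD=2) + P(IBD=1)/2.
#'
#' @param g a `genotypes` object with at least two samples.
#' @param freqs optional vector of allele_b frequencies (one per SNP) used as
#'   reference frequencies.
#' @return data.frame with columns sample_i, sample_j, p_ibd0, p_ibd1,
#'   p_ibd2, pi_hat.
#' @export
estimate_ibd <- function(g, freqs = NULL) {
  stopifnot(inherits(g, "genotypes"))
  n <- nrow(g$dosage)
  if (n < 2L) ps_stop("estimate_ibd needs >= 2 samples")
  d <- g$dosage
  p <- freqs %||% (colMeans(d, na.rm = TRUE) / 2)
  if (any(is.na(p))) ps_stop("estimate_ibd: SNP with no called genotypes")
  q <- 1 - p
  use <- p > 0 & p < 1
  d <- d[, use, drop = FALSE]; p <- p[use]; q <- q[use]
  # per-locus expected IBS-state probabilities conditional on IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- 1 - e0_ibd0 - e1_ibd0
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- 1 - e1_ibd1
  pairs <- utils::combn(n, 2)
  res <- apply(pairs, 2L, function(ij) {
    gi <- d[ij[1], ]; gj <- d[ij[2], ]
    ok <- !is.na(gi) & !is.na(gj)
    ibs <- 2L - abs(gi[ok] - gj[ok])
    N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L); N2 <- sum(ibs == 2L)
    s0 <- sum(e0_ibd0[ok]); s1_0 <- sum(e1_ibd0[ok]); s2_0 <- sum(e2_ibd0[ok])
    s1_1 <- sum(e1_ibd1[ok]); s2_1 <- sum(e2_ibd1[ok]); nl <- sum(ok)
    p0 <- if (s0 > 0) N0 / s0 else 0
    p1 <- if (s1_1 > 0) (N1 - p0 * s1_0) / s1_1 else 0
    p2 <- (N2 - p0 * s2_0 - p1 * s2_1) / nl
    v <- pmax(c(p0, p1, p2), 0)
    v <- v / sum(v)
    c(v, v[3] + v[2] / 2)
  })
  data.frame(sample_i = g$samples$sample_id[pairs[1, ]],
             sample_j = g$samples$sample_id[pairs[2, ]],
             p_ibd0 = res[1, ], p_ibd1 = res[2, ], p_ibd2 = res[3, ],
             pi_hat = res[4, ], stringsAsFactors = FALSE)
}

#' Greedy pruning of related individuals
#'
#' While any within-population pair exceeds `max_pi_hat`, removes the
#' individual involved in the most such pairs (ties broken by lower call
#' rate, then lexicographically smaller sample id).
#'
#' @param g a `genotypes` object.
#' @param pairs data.frame from [estimate_ibd()] computed on `g`.
#' @param max_pi_hat relatedness threshold (default 0.25).
#' @return list(genotypes, report); report detail lists removed ids.
#' @export
prune_related <- function(g, pairs, max_pi_hat = 0.25) {
  stopifnot(inherits(g, "genotypes"))
  pop <- stats::setNames(g$samples$population, g$samples$sample_id)
  call_rate <- stats::setNames(rowMeans(!is.na(g$dosage)), g$samples$sample_id)
  e <- pairs[pairs$pi_hat > max_pi_hat &
               pop[pairs$sample_i] == pop[pairs$sample_j], , drop = FALSE]
  removed <- character(0)
  while (nrow(e) > 0L) {
    deg <- table(c(e$sample_i, e$sample_j))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1L) {
      cr <- call_rate[cand]
      cand <- cand[cr == min(cr)]
      cand <- sort(cand)[1]
    }
    removed <- c(removed, cand)
    e <- e[e$sample_i != cand & e$sample_j != cand, , drop = FALSE]
  }
  keep <- !(g$samples$sample_id %in% removed)
  g2 <- subset_genotypes(g, samples = which(keep))
  rep <- new_qc_report("ibd_prune", list(max_pi_hat = max_pi_hat),
                       0L, length(removed), ncol(g2$dosage), nrow(g2$dosage),
                       detail = list(removed = removed))
  list(genotypes = g2, report = rep)
}

#' Squared genotype correlation (LD r2) between two SNPs
#'
#' Squared Pearson correlation of dosage vectors over the samples called at
#' both SNPs (composite LD; no phasing needed).
#'
#' @param g a `genotypes` object.
#' @param snp_i,snp_j SNP indices or snp_ids.
#' @return r-squared in \[0, 1\], or NA if either SNP is monomorphic among
#'   the jointly called samples.
#' @export
ld_r2 <- function(g, snp_i, snp_j) {
  if (is.character(snp_i)) snp_i <- match(snp_i, g$variants$snp_id)
  if (is.character(snp_j)) snp_j <- match(snp_j, g$variants$snp_id)
  x <- g$dosage[, snp_i]; y <- g$dosage[, snp_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0)
    return(NA_real_)
  stats::cor(x, y)^2
}

#' @keywords internal
#' @noRd
ld_r2_matrix <- function(dos, dos2 = NULL) {
  # (cross-)pairwise squared correlations of dosage columns; the fast BLAS
  # path applies when there are no missing calls
  complete <- !anyNA(dos) && (is.null(dos2) || !anyNA(dos2))
  r <- if (complete) suppressWarnings(stats::cor(dos, dos2))
  else suppressWarnings(stats::cor(dos, dos2, use = "pairwise.complete.obs"))
  r^2
}

#' Sliding-window LD pruning of SNPs
#'
#' Within each window of `window_snps` surviving SNPs (the window slides by
#' `step_snps`), pairs exceeding `r2_max` are resolved by removing the SNP of
#' the pair with the lower MAF (ties: the later position). Pairs are
#' processed in decreasing r2 order so the result is deterministic.
#'
#' @param g a `genotypes` object.
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps step in SNPs (default 5).
#' @param r2_max maximum allowed r2 within a window (default 0.5).
#' @return list(genotypes, report).
#' @export
ld_prune <- function(g, window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  stopifnot(inherits(g, "genotypes"), r2_max > 0, r2_max <= 1)
  v <- g$variants
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  alive <- rep(TRUE, ncol(g$dosage))
  for (ch in unique(v$chrom)) {
    idx_ch <- which(v$chrom == ch)
    start <- 1L
    repeat {
      cur <- idx_ch[alive[idx_ch]]
      if (length(cur) == 0L || start > length(cur)) break
      win <- cur[start:min(start + window_snps - 1L, length(cur))]
      if (length(win) >= 2L) {
        r2 <- ld_r2_matrix(g$dosage[, win, drop = FALSE])
        repeat {
          r2w <- r2[alive[win], alive[win], drop = FALSE]
          wl <- win[alive[win]]
          if (length(wl) < 2L) break
          r2w[lower.tri(r2w, diag = TRUE)] <- NA
          mx <- suppressWarnings(max(r2w, na.rm = TRUE))
          if (!is.finite(mx) || mx <= r2_max) break
          hit <- which(r2w == mx, arr.ind = TRUE)[1, ]
          a <- wl[hit[1]]; b <- wl[hit[2]]
          drop_snp <- if (maf[a] < maf[b]) a
          else if (maf[b] < maf[a]) b
          else if (v$pos[a] > v$pos[b]) a else b
          alive[drop_snp] <- FALSE
        }
      }
      if (start + window_snps - 1L >= length(idx_ch[alive[idx_ch]]) &&
          length(win) < window_snps) break
      start <- start + step_snps
      if (start > length(idx_ch)) break
    }
  }
  g2 <- subset_genotypes(g, snps = which(alive))
  rep <- new_qc_report("ld_prune",
                       list(window_snps = window_snps, step_snps = step_snps,
                            r2_max = r2_max),
                       sum(!alive), 0L, ncol(g2$dosage), nrow(g2$dosage))
  list(genotypes = g2, report = rep)
}

#' Run the full QC cascade
#'
#' Call-rate filter, then MAF/HWE filter, then IBD relatedness pruning
#' (within populations).
#'
#' @param g a `genotypes` object.
#' @param min_rate,min_maf,hwe_alpha,max_pi_hat thresholds (defaults 0.90,
#'   0.01, 1e-6, 0.25).
#' @return list(genotypes, reports = list of qc_report).
#' @export
qc_cascade <- function(g, min_rate = 0.90, min_maf = 0.01, hwe_alpha = 1e-6,
                       max_pi_hat = 0.25) {
  s1 <- filter_call_rate(g, min_rate)
  s2 <- filter_maf_hwe(s1$genotypes, min_maf, hwe_alpha)
  ibd <- estimate_ibd(s2$genotypes)
  s3 <- prune_related(s2$genotypes, ibd, max_pi_hat)
  list(genotypes = s3$genotypes,
       reports = list(call_rate = s1$report, maf_hwe = s2$report,
                      ibd_prune = s3$report))
}
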