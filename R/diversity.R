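# Population differentiation and diversity: allele frequencies, AFD, chord
# and Reynolds distances, Weir-Cockerham FST (per SNP and multilocus with a
# bootstrap CI), Z(FST), and the LD-decay curve.

#' Per-population allele frequencies
#'
#' @param g a `genotypes` object.
#' @return list with `p` (n_pop x M matrix of allele_b frequencies, NA where
#'   a population has no called genotype), `n_called` (n_pop x M diploid
#'   counts) and `populations`.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  pops <- sort(unique(g$samples$population))
  if (length(pops) == 0L) ps_stop("no populations")
  p <- matrix(NA_real_, length(pops), ncol(g$dosage),
              dimnames = list(pops, g$variants$snp_id))
  n_called <- matrix(0L, length(pops), ncol(g$dosage),
                     dimnames = list(pops, g$variants$snp_id))
  for (k in seq_along(pops)) {
    d <- g$dosage[g$samples$population == pops[k], , drop = FALSE]
    n_called[k, ] <- colSums(!is.na(d))
    p[k, ] <- colSums(d, na.rm = TRUE) / (2 * n_called[k, ])
    p[k, n_called[k, ] == 0L] <- NA_real_
  }
  list(p = p, n_called = n_called, populations = pops)
}

#' Absolute allele frequency difference between two populations
#'
#' Per SNP, AFD is half the sum of absolute per-allele frequency differences;
#' for biallelic loci this equals `|p1 - p2|`. SNPs with an undefined
#' frequency in either population are excluded from the summary.
#'
#' @param freqs output of [allele_frequencies()].
#' @param pop1,pop2 population labels.
#' @return list(per_snp, mean, sd, n_used, n_excluded).
#' @export
afd <- function(freqs, pop1, pop2) {
  p1 <- freqs$p[pop1, ]; p2 <- freqs$p[pop2, ]
  per_snp <- (abs(p1 - p2) + abs((1 - p1) - (1 - p2))) / 2
  ok <- !is.na(per_snp)
  list(per_snp = per_snp, mean = mean(per_snp[ok]), sd = stats::sd(per_snp[ok]),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Cavalli-Sforza and Edwards chord distance
#'
#' `D = (2 / (pi * m)) * sum_loci sqrt(2 * (1 - sum_alleles sqrt(x_i y_i)))`
#' over the m loci with defined frequencies in both populations.
#'
#' @inheritParams afd
#' @return chord distance (non-negative scalar).
#' @export
chord_distance <- function(freqs, pop1, pop2) {
  p1 <- freqs$p[pop1, ]; p2 <- freqs$p[pop2, ]
  ok <- !is.na(p1) & !is.na(p2)
  if (!any(ok)) ps_stop("chord_distance: no loci with defined frequencies")
  p1 <- p1[ok]; p2 <- p2[ok]
  cosang <- pmin(1, sqrt(p1 * p2) + sqrt((1 - p1) * (1 - p2)))
  (2 / (pi * length(p1))) * sum(sqrt(2 * (1 - cosang)))
}

#' Reynolds coancestry distance
#'
#' Reynolds, Weir & Cockerham's coancestry estimator theta, aggregated over
#' loci as a ratio of sums and transformed to `-ln(1 - theta)` (additive
#' under pure drift). Negative estimates are clipped at 0.
#'
#' @inheritParams afd
#' @param freqs output of [allele_frequencies()] (uses `n_called` for the
#'   sample-size correction).
#' @return non-negative distance.
#' @export
reynolds_distance <- function(freqs, pop1, pop2) {
  p1 <- freqs$p[pop1, ]; p2 <- freqs$p[pop2, ]
  n1 <- freqs$n_called[pop1, ]; n2 <- freqs$n_called[pop2, ]
  ok <- !is.na(p1) & !is.na(p2) & n1 > 1L & n2 > 1L
  if (!any(ok)) ps_stop("reynolds_distance: no usable loci")
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  # Method-of-moments coancestry in the Reynolds style. With E[p-hat_i] = p_i
  # and sampling variance p_i q_i / (2 n_i):
  #   num_l  = (p1-p2)^2 minus unbiased sampling terms  -> E = 2 theta p0 q0
  #   den_l  = 2 * (pbar qbar + (p1-p2)^2 / 4)          -> E = 2 p0 q0
  # theta = sum(num) / sum(den) is a ratio-of-sums estimator of the average
  # coancestry accumulated since divergence.
  v1 <- p1 * (1 - p1) / (2 * n1 - 1)
  v2 <- p2 * (1 - p2) / (2 * n2 - 1)
  num <- (p1 - p2)^2 - v1 - v2
  pbar <- (p1 + p2) / 2
  den <- 2 * (pbar * (1 - pbar) + (p1 - p2)^2 / 4)
  theta <- sum(num) / sum(den)
  if (!is.finite(theta)) ps_stop("reynolds_distance: degenerate denominator")
  theta <- max(0, theta)
  if (theta >= 1) ps_stop("reynolds_distance: theta >= 1 (%.4f)", theta)
  -log(1 - theta)
}

#' Pairwise distance matrix over all populations
#'
#' @param freqs output of [allele_frequencies()].
#' @param metric one of "chord", "reynolds", "afd_mean".
#' @return symmetric matrix with zero diagonal and a `metric` attribute.
#' @export
distance_matrix <- function(freqs, metric = c("chord", "reynolds", "afd_mean")) {
  metric <- match.arg(metric)
  pops <- freqs$populations
  f <- switch(metric,
              chord = function(a, b) chord_distance(freqs, a, b),
              reynolds = function(a, b) reynolds_distance(freqs, a, b),
              afd_mean = function(a, b) afd(freqs, a, b)$mean)
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- f(pops[i], pops[j])
  }
  attr(d, "metric") <- metric
  d
}

#' @keywords internal
#' @noRd
wc_components <- function(g, pop1, pop2) {
  # Weir & Cockerham (1984) variance components a, b, c per SNP, two pops.
  d <- g$dosage
  i1 <- g$samples$population == pop1
  i2 <- g$samples$population == pop2
  comp_pop <- function(idx) {
    dd <- d[idx, , drop = FALSE]
    n <- colSums(!is.na(dd))
    p <- colSums(dd, na.rm = TRUE) / (2 * n)
    h <- colSums(dd == 1L, na.rm = TRUE) / n
    list(n = n, p = p, h = h)
  }
  s1 <- comp_pop(i1); s2 <- comp_pop(i2)
  r <- 2
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)
  a <- nbar / nc * (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 < 2L | n2 < 2L | is.na(pbar)
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Per-SNP Weir-Cockerham FST between two populations
#'
#' theta-hat = a / (a + b + c) from the three variance components; may be
#' negative; NA where a + b + c = 0 (e.g. SNP monomorphic in both
#' populations).
#'
#' @param g a `genotypes` object.
#' @param pop1,pop2 population labels.
#' @return numeric vector of per-SNP theta estimates (named by snp_id).
#' @export
per_snp_wc_fst <- function(g, pop1, pop2) {
  w <- wc_components(g, pop1, pop2)
  denom <- w$a + w$b + w$c
  theta <- ifelse(!is.na(denom) & denom != 0, w$a / denom, NA_real_)
  stats::setNames(theta, g$variants$snp_id)
}

#' Multilocus Weir-Cockerham FST with bootstrap confidence interval
#'
#' Ratio-of-sums estimator `sum(a) / sum(a+b+c)` with a percentile CI from
#' bootstrap resampling of loci.
#'
#' @inheritParams per_snp_wc_fst
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list(theta, ci_low, ci_high, n_loci).
#' @export
pairwise_fst_multilocus <- function(g, pop1, pop2, n_boot = 1000L,
                                    conf = 0.95, seed = 1L) {
  stopifnot(n_boot >= 100L)
  w <- wc_components(g, pop1, pop2)
  ok <- !is.na(w$a)
  a <- w$a[ok]; den <- (w$a + w$b + w$c)[ok]
  if (length(a) < 2L) ps_stop("pairwise_fst_multilocus needs >= 2 usable SNPs")
  theta <- sum(a) / sum(den)
  set.seed(seed)
  m <- length(a)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(m, m, replace = TRUE)
    sum(a[idx]) / sum(den[idx])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  list(theta = theta, ci_low = ci[1], ci_high = ci[2], n_loci = m)
}

#' Z-transform of per-SNP FST values
#'
#' @param theta numeric vector (NAs allowed; preserved in the output).
#' @return vector of the same length with mean 0 and SD 1 over defined
#'   entries.
#' @export
zfst <- function(theta) {
  ok <- !is.na(theta)
  if (sum(ok) < 2L) ps_stop("zfst needs >= 2 defined values")
  s <- stats::sd(theta[ok])
  if (s == 0) ps_stop("zfst: zero variance")
  out <- theta
  out[ok] <- (theta[ok] - mean(theta[ok])) / s
  out
}

#' LD decay curve: mean r2 by physical distance
#'
#' Pairs SNPs within each chromosome up to `max_dist_bp`, computes composite
#' (dosage) r2, and averages within distance bins.
#'
#' @param g a `genotypes` object.
#' @param max_dist_bp maximum pair distance (default 1e6).
#' @param bin_width_bp bin width (default 1e5).
#' @return data.frame(bin_start, bin_end, mean_r2, n_pairs); `mean_r2` is NA
#'   for empty bins. The row covering 1e5 bp is the conventional "LD at
#'   100 kbps" summary.
#' @export
ld_decay_curve <- function(g, max_dist_bp = 1e6, bin_width_bp = 1e5) {
  stopifnot(inherits(g, "genotypes"))
  breaks <- seq(0, max_dist_bp, by = bin_width_bp)
  if (breaks[length(breaks)] < max_dist_bp) breaks <- c(breaks, max_dist_bp)
  nb <- length(breaks) - 1L
  sums <- numeric(nb); counts <- integer(nb)
  for (ch in unique(g$variants$chrom)) {
    vi <- which(g$variants$chrom == ch)
    if (length(vi) < 2L) next
    pos <- g$variants$pos[vi]
    r2 <- ld_r2_matrix(g$dosage[, vi, drop = FALSE])
    dmat <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dmat)
    d <- dmat[ut]; r <- r2[ut]
    sel <- d > 0 & d <= max_dist_bp & !is.na(r)
    if (!any(sel)) next
    bin <- findInterval(d[sel], breaks, left.open = TRUE, all.inside = TRUE)
    sums <- sums + vapply(seq_len(nb), function(b) sum(r[sel][bin == b]), numeric(1))
    counts <- counts + vapply(seq_len(nb), function(b) sum(bin == b), integer(1))
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             mean_r2 = ifelse(counts > 0L, sums / counts, NA_real_),
             n_pairs = counts)
}
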