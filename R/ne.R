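# Effective population size from linkage disequilibrium.
#
# Contemporary Ne: mean squared composite (Burrows-type, genotype-based)
# correlation over inter-chromosomal SNP pairs; the expected sampling
# contribution for S >= 30 diploids under random mating is removed using the
# constants of the cited LD-Ne literature (Waples 2006; Waples & Do 2008):
#   E[r2_sample] = 1/S + 3.19/S^2
#   Ne-hat       = (1/3 + sqrt(1/9 - 2.76 * r2_drift)) / (2 * r2_drift)
# Historical Ne: within-chromosome pairs binned by recombination distance c
# (Morgans); Ne(c) = (1/(4 f(c))) * (1/r2_adj - alpha) with linear f(c) = c
# by default, reported at t = 1/(2 f(c)) generations ago.

#' @keywords internal
#' @noRd
sampling_r2 <- function(S) 1 / S + 3.19 / S^2

#' @keywords internal
#' @noRd
ne_from_r2drift <- function(r2d) {
  # inversion of E[r2_drift] = 1/(3Ne) + 0.69/Ne^2 (random mating, S >= 30)
  if (is.na(r2d) || r2d <= 0) return(Inf)
  disc <- 1 / 9 - 2.76 * r2d
  if (disc < 0) disc <- 0
  (1 / 3 + sqrt(disc)) / (2 * r2d)
}

#' @keywords internal
#' @noRd
inter_chrom_r2 <- function(dos, chrom) {
  # mean r2 and pair count over all pairs of SNPs on different chromosomes,
  # accumulated block-wise per chromosome pair, plus per-chromosome sums for
  # the leave-one-chromosome-out jackknife
  chs <- unique(chrom)
  by_chrom <- stats::setNames(lapply(chs, function(ch) c(sum = 0, n = 0)), chs)
  tot_sum <- 0; tot_n <- 0
  for (i in seq_along(chs)) for (j in seq_along(chs)) {
    if (j <= i) next
    r2 <- ld_r2_matrix(dos[, chrom == chs[i], drop = FALSE],
                       dos[, chrom == chs[j], drop = FALSE])
    s <- sum(r2, na.rm = TRUE); n <- sum(!is.na(r2))
    tot_sum <- tot_sum + s; tot_n <- tot_n + n
    for (ch in c(chs[i], chs[j]))
      by_chrom[[ch]] <- by_chrom[[ch]] + c(sum = s, n = n)
  }
  list(sum = tot_sum, n = tot_n, by_chrom = by_chrom)
}

#' Contemporary effective population size from inter-chromosomal LD
#'
#' @param g a `genotypes` object.
#' @param population population label (default: all samples).
#' @param maf_screen exclude SNPs with MAF below this value (default 0.02;
#'   0 keeps all polymorphic SNPs).
#' @return list(ne_point, ci_low, ci_high, r2_mean, r2_drift, n_pairs,
#'   n_snps, S, maf_screen). `ne_point` is `Inf` when the drift component of
#'   r2 is non-positive. The CI is a leave-one-chromosome-out jackknife.
#' @export
contemporary_ldne <- function(g, population = NULL, maf_screen = 0.02) {
  stopifnot(inherits(g, "genotypes"))
  if (!is.null(population))
    g <- subset_genotypes(g, samples = which(g$samples$population == population))
  S <- nrow(g$dosage)
  if (S < 10L) ps_stop("contemporary_ldne: needs >= 10 samples, have %d", S)
  if (length(unique(g$variants$chrom)) < 2L)
    ps_stop("contemporary_ldne: needs >= 2 chromosomes")
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > 0 & maf >= maf_screen
  g <- subset_genotypes(g, snps = which(keep))
  dos <- g$dosage; storage.mode(dos) <- "double"
  agg <- inter_chrom_r2(dos, g$variants$chrom)
  if (agg$n < 100L)
    ps_warn("contemporary_ldne: only %d usable pairs", agg$n)
  # Burrows composite r2 = (S/(S-1))^2 x squared Pearson dosage correlation;
  # this is the estimator whose sampling expectation is 1/S + 3.19/S^2
  bc <- (S / (S - 1))^2
  r2_mean <- bc * agg$sum / agg$n
  r2_drift <- r2_mean - sampling_r2(S)
  ne <- ne_from_r2drift(r2_drift)
  # delete-one-chromosome jackknife on mean r2, transformed to Ne
  chs <- names(agg$by_chrom)
  ne_jack <- vapply(chs, function(ch) {
    s <- agg$sum - agg$by_chrom[[ch]]["sum"]
    n <- agg$n - agg$by_chrom[[ch]]["n"]
    if (n <= 0) return(NA_real_)
    ne_from_r2drift(bc * s / n - sampling_r2(S))
  }, numeric(1))
  ne_jack <- ne_jack[is.finite(ne_jack)]
  if (length(ne_jack) >= 2L && is.finite(ne)) {
    nj <- length(ne_jack)
    theta_dot <- mean(ne_jack)
    se <- sqrt((nj - 1) / nj * sum((ne_jack - theta_dot)^2))
    ci <- c(max(0, ne - stats::qt(0.975, nj - 1) * se),
            ne + stats::qt(0.975, nj - 1) * se)
  } else ci <- c(NA_real_, NA_real_)
  list(ne_point = ne, ci_low = ci[1], ci_high = ci[2],
       r2_mean = r2_mean, r2_drift = r2_drift, n_pairs = agg$n,
       n_snps = ncol(dos), S = S, maf_screen = maf_screen)
}

#' Batch contemporary Ne over the conventional MAF screens
#'
#' @param g a `genotypes` object.
#' @param populations population labels (default: all present).
#' @param maf_screens screens to run (default 0, 0.02, 0.05, 0.1).
#' @return data.frame keyed by population x maf_screen.
#' @export
contemporary_ldne_batch <- function(g, populations = NULL,
                                    maf_screens = c(0, 0.02, 0.05, 0.1)) {
  populations <- populations %||% sort(unique(g$samples$population))
  rows <- list()
  for (pp in populations) for (ms in maf_screens) {
    est <- contemporary_ldne(g, pp, ms)
    rows[[length(rows) + 1L]] <-
      data.frame(population = pp, maf_screen = ms, ne = est$ne_point,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 n_pairs = est$n_pairs, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Historical effective population size from distance-binned LD
#'
#' Within-chromosome SNP pairs are binned by recombination distance
#' (Morgans, from physical distance via `cm_per_mb`); each bin's
#' sample-adjusted mean r2 yields the Ne prevailing about `1/(2c)`
#' generations ago.
#'
#' @param g a `genotypes` object.
#' @param population population label (default: all samples).
#' @param max_dist_bp maximum pair distance (default 4e6, i.e. 4000 kbps).
#' @param n_bins number of distance bins (default 20).
#' @param cm_per_mb recombination map density (default 1 cM/Mb).
#' @param alpha mutation adjustment: 2 (none, default) or 2.2.
#' @param mapping "linear" (f(c) = c, default) or "sved"
#'   (f(c) = (1 - exp(-2c))/2).
#' @return data.frame(generations_ago, ne, c_low, c_high, mean_r2_adj,
#'   n_pairs), sorted by increasing generations_ago; bins whose adjusted r2
#'   is non-positive are skipped with a warning.
#' @export
historical_ne <- function(g, population = NULL, max_dist_bp = 4e6,
                          n_bins = 20L, cm_per_mb = 1, alpha = 2,
                          mapping = c("linear", "sved")) {
  mapping <- match.arg(mapping)
  stopifnot(inherits(g, "genotypes"))
  if (!is.null(population))
    g <- subset_genotypes(g, samples = which(g$samples$population == population))
  S <- nrow(g$dosage)
  breaks <- seq(0, max_dist_bp, length.out = n_bins + 1L)
  sums <- numeric(n_bins); counts <- integer(n_bins)
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
    for (b in unique(bin)) {
      sums[b] <- sums[b] + sum(r[sel][bin == b])
      counts[b] <- counts[b] + sum(bin == b)
    }
  }
  rows <- list()
  for (b in seq_len(n_bins)) {
    if (counts[b] == 0L) next
    mid_bp <- (breaks[b] + breaks[b + 1]) / 2
    c_mid <- mid_bp / 1e6 * cm_per_mb / 100       # Morgans
    fc <- if (mapping == "linear") c_mid else (1 - exp(-2 * c_mid)) / 2
    r2_adj <- (S / (S - 1))^2 * sums[b] / counts[b] - sampling_r2(S)
    if (r2_adj <= 0) {
      ps_warn("historical_ne: bin %d has non-positive adjusted r2; skipped", b)
      next
    }
    ne <- (1 / (4 * fc)) * (1 / r2_adj - alpha)
    if (ne <= 0) next
    rows[[length(rows) + 1L]] <-
      data.frame(generations_ago = 1 / (2 * fc), ne = ne,
                 c_low = breaks[b] / 1e6 * cm_per_mb / 100,
                 c_high = breaks[b + 1] / 1e6 * cm_per_mb / 100,
                 mean_r2_adj = r2_adj, n_pairs = counts[b])
  }
  out <- do.call(rbind, rows)
  out[order(out$generations_ago), , drop = FALSE]
}
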