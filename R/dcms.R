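# De-correlated composite of multiple signals (DCMS): fractional-rank
# right-tailed p-values per statistic, a robust (minimum covariance
# determinant) estimate of the correlation between statistics, the DCMS
# combination
#   DCMS_i = sum_k ln((1 - p_ik) / p_ik) / sum_l |r_kl|,
# a robust-normal calibration of the composite, and Benjamini-Hochberg
# false-discovery control.

#' Fractional-rank right-tailed p-values
#'
#' `p_i = rank of x_i in descending order / (n + 1)`; the largest statistic
#' gets `1/(n+1)`, ties share the mean rank, and all p are strictly inside
#' (0, 1) so the DCMS logit is finite.
#'
#' @param x numeric vector (NAs preserved).
#' @return p-value vector of the same length.
#' @export
fractional_rank_pvalues <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) ps_stop("fractional_rank_pvalues: needs >= 2 values")
  out <- rep(NA_real_, length(x))
  n <- sum(ok)
  out[ok] <- rank(-x[ok], ties.method = "average") / (n + 1)
  out
}

#' Robust correlation of selection statistics via FAST-MCD
#'
#' Minimum covariance determinant estimate of the covariance of the columns
#' of `x`, converted to a correlation matrix. Implements FAST-MCD: seeded
#' random elemental starts, concentration (C-) steps to convergence on the
#' best candidates. Rows with any missing entry are dropped; at most
#' `subsample` rows are used.
#'
#' @param x numeric matrix (SNPs x statistics).
#' @param alpha subset fraction (default 0.75).
#' @param subsample maximum rows used (default 30000).
#' @param seed RNG seed for subsampling and starts.
#' @param n_starts number of random starts (default 100).
#' @return correlation matrix (K x K) with attribute `mcd_cov` (the raw MCD
#'   covariance of the best subset).
#' @export
mcd_covariance <- function(x, alpha = 0.75, subsample = 30000L, seed = 1L,
                           n_starts = 100L) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  m <- nrow(x); k <- ncol(x)
  if (m < max(3L, k + 1L)) ps_stop("mcd_covariance: too few complete rows (%d)", m)
  set.seed(seed)
  if (m > subsample) {
    x <- x[sample.int(m, subsample), , drop = FALSE]
    m <- nrow(x)
  }
  h <- ceiling(alpha * m)
  cstep <- function(mu, sigma) {
    si <- tryCatch(solve(sigma), error = function(e) NULL)
    if (is.null(si)) return(NULL)
    d2 <- stats::mahalanobis(x, mu, sigma)
    idx <- order(d2)[seq_len(h)]
    list(mu = colMeans(x[idx, , drop = FALSE]),
         sigma = stats::cov(x[idx, , drop = FALSE]), idx = idx)
  }
  run_to_convergence <- function(mu, sigma, max_iter = 50L) {
    last_det <- Inf
    st <- list(mu = mu, sigma = sigma)
    for (it in seq_len(max_iter)) {
      st2 <- cstep(st$mu, st$sigma)
      if (is.null(st2)) return(NULL)
      dt <- det(st2$sigma)
      if (dt <= 0 || abs(last_det - dt) < 1e-12 * max(1, abs(dt))) {
        st2$det <- dt
        return(st2)
      }
      last_det <- dt
      st <- st2
    }
    st$det <- last_det
    st
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    el <- x[sample.int(m, k + 1L), , drop = FALSE]
    mu0 <- colMeans(el); s0 <- stats::cov(el)
    grow <- k + 1L
    while ((!is.finite(det(s0)) || det(s0) <= 0) && grow < m) {
      grow <- min(m, grow * 2L)
      el <- x[sample.int(m, grow), , drop = FALSE]
      mu0 <- colMeans(el); s0 <- stats::cov(el)
    }
    st <- run_to_convergence(mu0, s0)
    if (is.null(st) || !is.finite(st$det) || st$det <= 0) next
    if (is.null(best) || st$det < best$det) best <- st
  }
  if (is.null(best)) {
    ps_warn("mcd_covariance: degenerate MCD subsets; falling back to classical covariance")
    cv <- stats::cov(x)
    r <- stats::cov2cor(cv)
    attr(r, "mcd_cov") <- cv
    return(r)
  }
  # consistency factor for normal data (irrelevant to the correlation but
  # kept so mcd_cov is on the right scale)
  q <- stats::qchisq(h / m, df = k)
  cf <- (h / m) / stats::pchisq(q, df = k + 2)
  cv <- best$sigma * cf
  r <- stats::cov2cor(cv)
  attr(r, "mcd_cov") <- cv
  r
}

#' DCMS composite statistic
#'
#' @param frac_p matrix (M x K) of fractional-rank p-values strictly in
#'   (0, 1); rows with NA return NA.
#' @param correlation K x K correlation matrix of the statistics.
#' @return numeric vector of DCMS values (length M).
#' @export
dcms <- function(frac_p, correlation) {
  frac_p <- as.matrix(frac_p)
  k <- ncol(frac_p)
  correlation <- as.matrix(correlation)
  stopifnot(nrow(correlation) == k, ncol(correlation) == k)
  if (max(abs(correlation - t(correlation))) > 1e-8 ||
      any(abs(diag(correlation) - 1) > 1e-8))
    ps_stop("dcms: correlation must be symmetric with unit diagonal")
  vals <- frac_p[!is.na(frac_p)]
  if (any(vals <= 0 | vals >= 1))
    ps_stop("dcms: fractional p-values must be strictly inside (0, 1)")
  w <- colSums(abs(correlation))
  logits <- log((1 - frac_p) / frac_p)
  as.numeric(logits %*% (1 / w))
}

#' Calibrate DCMS values against a robust normal fit
#'
#' Robust location/scale by intercept-only M-estimation (Huber psi,
#' c = 1.345, MAD scale; `MASS::rlm`); p-values are upper-tail normal
#' probabilities under the fitted location and scale.
#'
#' @param d numeric vector of DCMS values (NAs preserved).
#' @return list(p, mu, sigma).
#' @export
calibrate_dcms <- function(d) {
  ok <- !is.na(d)
  if (sum(ok) < 10L) ps_stop("calibrate_dcms: needs >= 10 values")
  if (stats::mad(d[ok]) == 0) ps_stop("calibrate_dcms: zero MAD")
  fit <- MASS::rlm(d[ok] ~ 1, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 200, acc = 1e-8)
  mu <- unname(stats::coef(fit)[1])
  sigma <- fit$s
  p <- rep(NA_real_, length(d))
  p[ok] <- stats::pnorm(d[ok], mean = mu, sd = sigma, lower.tail = FALSE)
  list(p = p, mu = mu, sigma = sigma)
}

#' Benjamini-Hochberg q-values and significance calls
#'
#' @param p p-value vector (NAs preserved).
#' @param q_threshold significance level (default 0.05; strict `<`).
#' @return list(q, significant) where `significant` is a logical vector.
#' @export
bh_fdr <- function(p, q_threshold = 0.05) {
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q < q_threshold)
}
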