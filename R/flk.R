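# FLK: the Lewontin-Krakauer test extended with a population kinship matrix
# derived from a neighbor-joining tree of Reynolds distances. The kinship
# entry F_ij is the branch length shared by the root-to-leaf paths of
# populations i and j; the diagonal is each population's full root-to-leaf
# drift. Under neutrality the statistic is chi-squared with n_pop - 1
# degrees of freedom.

#' Neighbor-joining population tree from a Reynolds distance matrix
#'
#' For three or more populations this is standard NJ (negative branch
#' lengths clipped to zero) rooted at the midpoint; for two populations the
#' distance is split equally across the two branches.
#'
#' @param d symmetric distance matrix with population row/col names.
#' @return a rooted `phylo` object (ape).
#' @export
build_population_tree <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) ps_stop("build_population_tree: non-finite distances")
  n <- nrow(d)
  if (n < 2L) ps_stop("build_population_tree: needs >= 2 populations")
  labs <- rownames(d) %||% paste0("pop", seq_len(n))
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        labs[1], d[1, 2] / 2,
                                        labs[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  n_neg <- sum(tr$edge.length < 0)
  if (n_neg > 0L) {
    message(sprintf("build_population_tree: clipped %d negative branch length(s)", n_neg))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  phangorn::midpoint(tr)
}

#' Kinship matrix from a rooted population tree
#'
#' `F[i, j]` is the summed length of branches shared by the root-to-i and
#' root-to-j paths; `F[i, i]` is the full root-to-leaf path length. This is
#' exactly the phylogenetic variance-covariance matrix of the tree.
#'
#' @param tree a rooted `phylo` object.
#' @return symmetric positive semi-definite matrix with population names.
#' @export
kinship_from_tree <- function(tree) {
  if (!ape::is.rooted(tree))
    ps_stop("kinship_from_tree: tree must be rooted (midpoint-root it first)")
  f <- ape::vcv(tree)
  f[f < 0] <- 0
  (f + t(f)) / 2
}

#' FLK test across SNPs
#'
#' For each SNP with frequencies p (one per population),
#' `p0 = (1' F^-1 p) / (1' F^-1 1)`, `V = F p0 (1 - p0)` and
#' `T = (p - p0)' V^-1 (p - p0)`, with an upper-tail chi-squared p-value on
#' `n_pop - 1` degrees of freedom. SNPs whose estimated ancestral frequency
#' is 0 or 1 (fixed everywhere) are returned as NA.
#'
#' @param p matrix of allele frequencies (n_pop x M) with population
#'   rownames matching `F`, or a vector for a single SNP.
#' @param F kinship matrix from [kinship_from_tree()].
#' @return list(stat, p_value) vectors of length M.
#' @export
flk_test <- function(p, F) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  if (!is.null(rownames(p)) && !is.null(rownames(F))) {
    if (!setequal(rownames(p), rownames(F)))
      ps_stop("flk_test: population sets of p and F differ")
    p <- p[rownames(F), , drop = FALSE]
  }
  npop <- nrow(F)
  kap <- kappa(F)
  Finv <- tryCatch(solve(F), error = function(e)
    ps_stop("flk_test: singular kinship matrix (condition number %.3g)", kap))
  u <- colSums(Finv)          # Finv %*% 1, as a vector (Finv symmetric)
  denom <- sum(u)
  p0 <- as.numeric(u %*% p) / denom
  D <- p - matrix(p0, npop, ncol(p), byrow = TRUE)
  qf <- colSums(D * (Finv %*% D))
  v <- p0 * (1 - p0)
  stat <- ifelse(v > 0, qf / v, NA_real_)
  fixed <- p0 <= 0 | p0 >= 1 | apply(is.na(p), 2, any)
  stat[fixed] <- NA_real_
  pv <- stats::pchisq(stat, df = npop - 1, lower.tail = FALSE)
  list(stat = as.numeric(stat), p_value = as.numeric(pv))
}
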