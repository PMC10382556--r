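# Population structure: PCA on standardized dosages, local-outlier-factor
# screening on the leading PCs, identity-by-state dissimilarity and
# average-linkage hierarchical clustering.

#' Principal component analysis of standardized genotypes
#'
#' Columns are centered and scaled to unit variance (zero-variance SNPs are
#' dropped first; sporadic missing dosages are mean-imputed per SNP, the one
#' place in the package where imputation is used, because scaling requires
#' complete columns). Scores follow a deterministic sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param g a `genotypes` object.
#' @param k number of components to retain.
#' @return list(scores, explained_variance, loadings, n_snps_used,
#'   n_imputed).
#' @export
pca_genotypes <- function(g, k = 10L) {
  stopifnot(inherits(g, "genotypes"))
  x <- g$dosage
  storage.mode(x) <- "double"
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0L) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  v <- apply(x, 2L, stats::var)
  keep <- v > 0
  if (sum(keep) < k) ps_stop("pca: k = %d exceeds number of variable SNPs (%d)",
                             k, sum(keep))
  x <- x[, keep, drop = FALSE]
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  if (k > ncol(pr$x)) ps_stop("pca: k = %d exceeds rank %d", k, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- g$samples$sample_id
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, explained_variance = ev[seq_len(k)],
       loadings = load, n_snps_used = sum(keep), n_imputed = n_imputed)
}

#' @keywords internal
#' @noRd
lof_scores <- function(x, k_neighbors) {
  # Breunig et al. local outlier factor, brute force on a distance matrix.
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  d[d < 1e-12] <- 1e-12    # distance floor for duplicate points
  diag(d) <- Inf
  knn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  kdist <- vapply(seq_len(n), function(i) d[i, knn[i, k_neighbors]], numeric(1))
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[knn[i, ]], d[i, knn[i, ]])
    1 / mean(reach)
  }, numeric(1))
  vapply(seq_len(n), function(i) mean(lrd[knn[i, ]]) / lrd[i], numeric(1))
}

#' Local-outlier-factor screening of PCA scores
#'
#' Applies LOF within each labeled population on the supplied score matrix
#' (conventionally the first three PCs) and flags samples whose LOF exceeds
#' `threshold`.
#'
#' @param scores numeric matrix with sample_id rownames (e.g.
#'   `pca_genotypes(g, 3)$scores`).
#' @param population character vector of population labels (same order as
#'   rows), or NULL to treat all samples as one group.
#' @param k_neighbors neighborhood size (default 20; capped at group size
#'   minus 1).
#' @param threshold flagging threshold (default 1.5).
#' @return data.frame(sample_id, population, lof_score, flagged).
#' @export
lof_outliers <- function(scores, population = NULL, k_neighbors = 20L,
                         threshold = 1.5) {
  n <- nrow(scores)
  if (is.null(population)) population <- rep("all", n)
  stopifnot(length(population) == n, k_neighbors >= 2L)
  out <- numeric(n)
  for (pp in unique(population)) {
    idx <- which(population == pp)
    if (length(idx) < 3L) { out[idx] <- 1; next }
    k <- min(k_neighbors, length(idx) - 1L)
    out[idx] <- lof_scores(scores[idx, , drop = FALSE], k)
  }
  data.frame(sample_id = rownames(scores) %||% as.character(seq_len(n)),
             population = population, lof_score = out,
             flagged = out > threshold, stringsAsFactors = FALSE)
}

#' Identity-by-state dissimilarity between all sample pairs
#'
#' `d(i, j) = 1 - mean(IBS / 2)` over jointly called SNPs, with
#' `IBS = 2 - |dosage_i - dosage_j|`.
#'
#' @param g a `genotypes` object.
#' @return symmetric N x N matrix in \[0, 1\] with zero diagonal; NA for
#'   pairs with no jointly called SNPs.
#' @export
ibs_dissimilarity <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  n <- nrow(g$dosage)
  if (n < 2L) ps_stop("ibs_dissimilarity needs >= 2 samples")
  x <- g$dosage
  storage.mode(x) <- "double"
  called <- !is.na(x)
  x0 <- x; x0[!called] <- 0
  # sum |gi - gj| over joint calls decomposes via indicator matrices
  n_joint <- called %*% t(called)
  abs_sum <- matrix(0, n, n)
  for (a in 0:2) for (b in 0:2) {
    if (a == b) next
    ia <- (x0 == a & called) * 1
    ib <- (x0 == b & called) * 1
    abs_sum <- abs_sum + abs(a - b) * ia %*% t(ib)
  }
  d <- abs_sum / (2 * n_joint)
  d[n_joint == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(g$samples$sample_id, g$samples$sample_id)
  d
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return an `hclust` object (heights non-decreasing toward the root).
#' @export
hierarchical_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d)), na.rm = TRUE) > 1e-8)
    ps_stop("hierarchical_tree: input must be a symmetric dissimilarity matrix")
  if (nrow(d) == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                          order = 1L, labels = rownames(d),
                          method = "average"),
                     class = "hclust"))
  }
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object from [hierarchical_tree()].
#' @param path optional file path to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
tree_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
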