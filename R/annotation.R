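# Candidate-gene / QTL annotation: interval overlap of significant SNPs
# (merged into runs of consecutive significant SNPs) with features extended
# by a regulatory flank, and hypergeometric gene-set enrichment with BH FDR.

#' Read a feature table from BED or GFF3
#'
#' BED's 0-based half-open coordinates are converted to the package's
#' 1-based inclusive convention; GFF3 is used as-is. Parsing is delegated to
#' rtracklayer.
#'
#' @param path file path (.bed, .gff/.gff3).
#' @param feature_class label stored in the result (default "gene").
#' @return data.frame(feature_id, chrom, start_bp, end_bp, feature_class).
#' @export
read_features <- function(path, feature_class = "gene") {
  if (!file.exists(path)) ps_stop("feature file not found: %s", path)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    ps_stop("read_features requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  ids <- gr$Name %||% gr$name %||% gr$ID %||% gr$gene_id
  if (is.null(ids) || all(is.na(ids)))
    ids <- paste0("feature", seq_along(gr))
  data.frame(feature_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             feature_class = feature_class, stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
merge_significant_intervals <- function(sig, variants) {
  # runs of consecutive (in the variant map) significant SNPs -> intervals
  if (is.null(variants)) {
    return(data.frame(chrom = sig$chrom, start_bp = sig$pos, end_bp = sig$pos,
                      n_snps = 1L, stringsAsFactors = FALSE))
  }
  out <- list()
  for (ch in unique(sig$chrom)) {
    vi <- variants[variants$chrom == ch, , drop = FALSE]
    flag <- vi$snp_id %in% sig$snp_id[sig$chrom == ch]
    if (!any(flag)) next
    r <- rle(flag)
    ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start_bp = vi$pos[begs[k]],
                   end_bp = vi$pos[ends[k]], n_snps = ends[k] - begs[k] + 1L,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Overlap significant SNPs with features (genes / QTL)
#'
#' Consecutive significant SNPs are first merged into intervals; an interval
#' hits a feature when it intersects `[start - flank, end + flank]`.
#'
#' @param sig_snps data.frame with columns snp_id, chrom, pos (the
#'   significant SNPs).
#' @param features data.frame from [read_features()] (or with the same
#'   columns).
#' @param flank_bp regulatory flank (default 40000).
#' @param variants full variant table (needed to define "consecutive");
#'   NULL treats each SNP as its own interval.
#' @return data.frame of hits: interval columns plus feature columns.
#' @export
overlap_features <- function(sig_snps, features, flank_bp = 40000,
                             variants = NULL) {
  if (nrow(sig_snps) == 0L)
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      feature_id = character(0),
                      feature_class = character(0)))
  iv <- merge_significant_intervals(sig_snps, variants)
  hits <- list()
  for (i in seq_len(nrow(iv))) {
    f <- features[features$chrom == iv$chrom[i] &
                    features$end_bp + flank_bp >= iv$start_bp[i] &
                    features$start_bp - flank_bp <= iv$end_bp[i], , drop = FALSE]
    if (nrow(f) == 0L) next
    hits[[length(hits) + 1L]] <-
      cbind(iv[rep(i, nrow(f)), , drop = FALSE],
            f[, c("feature_id", "feature_class"), drop = FALSE])
  }
  if (length(hits)) {
    out <- do.call(rbind, hits)
    rownames(out) <- NULL
    out
  } else {
    data.frame(chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), n_snps = integer(0),
               feature_id = character(0), feature_class = character(0))
  }
}

#' Hypergeometric gene-set enrichment with BH FDR
#'
#' Upper-tail hypergeometric p per gene set (probability of observing at
#' least the hit overlap by chance given the universe), BH-adjusted across
#' tested sets.
#'
#' @param hit_genes character vector of hit gene ids (must be a subset of
#'   the universe).
#' @param universe_genes character vector defining the universe.
#' @param gene_sets named list of character vectors, or a two-column
#'   data.frame (set_id, gene_id).
#' @param min_hits sets with fewer hit genes are skipped (default 2).
#' @return data.frame(set_id, set_size, n_hits, p, q) sorted by p.
#' @export
hypergeom_enrichment <- function(hit_genes, universe_genes, gene_sets,
                                 min_hits = 2L) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0L) ps_stop("empty gene universe")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe_genes))
    ps_stop("hit genes must be a subset of the universe")
  if (is.data.frame(gene_sets))
    gene_sets <- split(as.character(gene_sets[[2]]), gene_sets[[1]])
  rows <- list()
  for (set_id in names(gene_sets)) {
    set <- intersect(unique(gene_sets[[set_id]]), universe_genes)
    if (length(set) == 0L) next
    k <- length(hit_genes)
    x <- length(intersect(hit_genes, set))
    if (x < min_hits) next
    p <- stats::phyper(x - 1, length(set), length(universe_genes) - length(set),
                       k, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(set_id = set_id, set_size = length(set), n_hits = x, p = p,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set_id = character(0), set_size = integer(0),
                      n_hits = integer(0), p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
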