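# Runs of homozygosity: sliding-window scanline detection, genomic
# inbreeding (F_ROH), length-class summaries and shared-ROH incidence peaks.

#' ROH detection parameters
#'
#' Defaults follow common sliding-window practice for medium-density arrays:
#' 15-SNP windows, at most one heterozygote and one missing call per window,
#' a SNP is "in run" when at least 5% of the windows covering it are
#' homozygous, and candidate runs must have >= 20 SNPs, >= 500 kbps, at
#' least one SNP per 168 kbps of span, and no internal gap above 1 Mbps.
#'
#' @param window_size_snps,min_snp,overlap_threshold,min_density_bp_per_snp,max_gap_bp,min_length_bp,max_het_per_window,max_miss_per_window see description.
#' @return list of validated parameters.
#' @export
roh_params <- function(window_size_snps = 15L, min_snp = 20L,
                       overlap_threshold = 0.05,
                       min_density_bp_per_snp = 168000,
                       max_gap_bp = 1e6, min_length_bp = 5e5,
                       max_het_per_window = 1L, max_miss_per_window = 1L) {
  p <- list(window_size_snps = as.integer(window_size_snps),
            min_snp = as.integer(min_snp),
            overlap_threshold = overlap_threshold,
            min_density_bp_per_snp = min_density_bp_per_snp,
            max_gap_bp = max_gap_bp, min_length_bp = min_length_bp,
            max_het_per_window = as.integer(max_het_per_window),
            max_miss_per_window = as.integer(max_miss_per_window))
  stopifnot(p$window_size_snps > 0, p$min_snp > 0,
            p$overlap_threshold > 0, p$overlap_threshold <= 1,
            p$min_density_bp_per_snp > 0, p$max_gap_bp > 0,
            p$min_length_bp > 0)
  p
}

#' @keywords internal
#' @noRd
detect_roh_one_chrom <- function(geno, pos, chrom, sample_id, p) {
  m <- length(geno)
  w <- p$window_size_snps
  if (m < w) return(NULL)
  het <- as.integer(!is.na(geno) & geno == 1L)
  mis <- as.integer(is.na(geno))
  ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
  nw <- m - w + 1L
  starts <- seq_len(nw)
  win_hom <- (ch[starts + w] - ch[starts]) <= p$max_het_per_window &
    (cm[starts + w] - cm[starts]) <= p$max_miss_per_window
  # windows covering SNP j start in [j - w + 1, j] intersected with [1, nw]
  cw <- cumsum(c(0L, as.integer(win_hom)))
  lo <- pmax(1L, seq_len(m) - w + 1L)
  hi <- pmin(nw, seq_len(m))
  n_cov <- hi - lo + 1L
  n_hom <- cw[hi + 1L] - cw[lo]
  in_run <- n_cov > 0L & (n_hom / n_cov) >= p$overlap_threshold
  if (!any(in_run)) return(NULL)
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    idx <- begs[k]:ends[k]
    # split candidate at gaps above max_gap_bp
    gap_break <- which(diff(pos[idx]) > p$max_gap_bp)
    parts <- split(idx, findInterval(seq_along(idx), gap_break + 1L) + 0L)
    for (part in parts) {
      n_snps <- length(part)
      len <- pos[part[n_snps]] - pos[part[1]] + 1L
      if (n_snps >= p$min_snp && len >= p$min_length_bp &&
          len / n_snps <= p$min_density_bp_per_snp) {
        segs[[length(segs) + 1L]] <-
          data.frame(sample_id = sample_id, chrom = chrom,
                     start_bp = pos[part[1]], end_bp = pos[part[n_snps]],
                     n_snps = n_snps, length_bp = len,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

#' Detect runs of homozygosity
#'
#' Sliding-window scanline method: a window is homozygous when it contains at
#' most `max_het_per_window` heterozygotes and `max_miss_per_window` missing
#' calls; a SNP is in a run when the fraction of covering windows that are
#' homozygous reaches `overlap_threshold`; maximal runs of in-run SNPs are
#' split at large gaps and filtered by SNP count, length and density.
#'
#' @param g a `genotypes` object (positions sorted; enforced by the class).
#' @param samples sample ids to scan (default all).
#' @param params from [roh_params()].
#' @return data.frame of segments (sample_id, chrom, start_bp, end_bp,
#'   n_snps, length_bp); zero rows when nothing is found.
#' @export
detect_roh <- function(g, samples = NULL, params = roh_params()) {
  stopifnot(inherits(g, "genotypes"))
  samples <- samples %||% g$samples$sample_id
  out <- list()
  chroms <- unique(g$variants$chrom)
  for (s in samples) {
    si <- match(s, g$samples$sample_id)
    if (is.na(si)) ps_stop("unknown sample id: %s", s)
    for (ch in chroms) {
      vi <- which(g$variants$chrom == ch)
      seg <- detect_roh_one_chrom(g$dosage[si, vi], g$variants$pos[vi],
                                  ch, s, params)
      if (!is.null(seg)) out[[length(out) + 1L]] <- seg
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(sample_id = character(0), chrom = character(0),
                  start_bp = integer(0), end_bp = integer(0),
                  n_snps = integer(0), length_bp = integer(0))
}

#' Genome length covered by the SNP map
#'
#' Sum over chromosomes of (last SNP position - first SNP position); the
#' denominator of F_ROH.
#'
#' @param g a `genotypes` object.
#' @return length in base pairs.
#' @export
map_genome_length <- function(g) {
  sum(vapply(unique(g$variants$chrom), function(ch) {
    p <- g$variants$pos[g$variants$chrom == ch]
    diff(range(p))
  }, numeric(1)))
}

#' Genomic inbreeding coefficient from ROH segments
#'
#' `F_ROH = sum(segment lengths) / genome_length`.
#'
#' @param segments data.frame of one sample's segments (from
#'   [detect_roh()]).
#' @param genome_length_bp total map length (see [map_genome_length()]).
#' @return fraction in \[0, 1\].
#' @export
froh <- function(segments, genome_length_bp) {
  stopifnot(genome_length_bp > 0)
  if (nrow(segments) == 0L) return(0)
  for (ch in unique(segments$chrom)) for (s in unique(segments$sample_id)) {
    seg <- segments[segments$chrom == ch & segments$sample_id == s, , drop = FALSE]
    if (nrow(seg) > 1L) {
      seg <- seg[order(seg$start_bp), ]
      if (any(seg$start_bp[-1] <= seg$end_bp[-nrow(seg)]))
        ps_stop("froh: overlapping segments for sample %s chrom %s", s, ch)
    }
  }
  sum(segments$length_bp) / genome_length_bp
}

#' ROH summary per population
#'
#' Counts segments in the five conventional length classes ([0,4), [4,8),
#' [8,16), [16,32), >=32 Mb) and reports per-sample F_ROH.
#'
#' @param g a `genotypes` object (provides populations and the map length).
#' @param segments data.frame from [detect_roh()] over all samples.
#' @return list(class_counts = population x class table,
#'   froh = data.frame(sample_id, population, froh)).
#' @export
roh_summary <- function(g, segments) {
  glen <- map_genome_length(g)
  pop <- stats::setNames(g$samples$population, g$samples$sample_id)
  brk <- c(0, 4, 8, 16, 32, Inf) * 1e6
  lab <- c("0-4Mb", "4-8Mb", "8-16Mb", "16-32Mb", ">=32Mb")
  cls <- cut(segments$length_bp, brk, labels = lab, right = FALSE)
  class_counts <- table(population = pop[segments$sample_id], class = cls)
  fr <- vapply(g$samples$sample_id, function(s)
    froh(segments[segments$sample_id == s, , drop = FALSE], glen), numeric(1))
  list(class_counts = class_counts,
       froh = data.frame(sample_id = g$samples$sample_id,
                         population = g$samples$population,
                         froh = unname(fr), stringsAsFactors = FALSE))
}

#' Per-SNP ROH incidence and shared-ROH peaks
#'
#' Incidence at a SNP is the fraction of the population's individuals whose
#' ROH segments cover it; maximal runs of SNPs with incidence strictly above
#' `threshold` are reported as peaks.
#'
#' @param segments ROH segments of one population.
#' @param g a `genotypes` object restricted to (or containing) that
#'   population.
#' @param sample_ids the population's sample ids (denominator of the
#'   incidence).
#' @param threshold sharing threshold (default 0.7, strict `>`).
#' @return list(incidence = data.frame(snp_id, chrom, pos, incidence),
#'   peaks = data.frame(chrom, start_bp, end_bp, n_snps, max_incidence)).
#' @export
roh_incidence_peaks <- function(segments, g, sample_ids, threshold = 0.7) {
  v <- g$variants
  n_ind <- length(sample_ids)
  cov_count <- integer(nrow(v))
  seg <- segments[segments$sample_id %in% sample_ids, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    hit <- v$chrom == seg$chrom[i] & v$pos >= seg$start_bp[i] &
      v$pos <= seg$end_bp[i]
    cov_count[hit] <- cov_count[hit] + 1L
  }
  inc <- cov_count / n_ind
  peaks <- list()
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    above <- inc[vi] > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- vi[begs[k]:ends[k]]
      peaks[[length(peaks) + 1L]] <-
        data.frame(chrom = ch, start_bp = v$pos[idx[1]],
                   end_bp = v$pos[idx[length(idx)]], n_snps = length(idx),
                   max_incidence = max(inc[idx]), stringsAsFactors = FALSE)
    }
  }
  list(incidence = data.frame(snp_id = v$snp_id, chrom = v$chrom,
                              pos = v$pos, incidence = inc,
                              stringsAsFactors = FALSE),
       peaks = if (length(peaks)) do.call(rbind, peaks)
       else data.frame(chrom = character(0), start_bp = integer(0),
                       end_bp = integer(0), n_snps = integer(0),
                       max_incidence = numeric(0)))
}
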