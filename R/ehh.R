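# Extended haplotype homozygosity (EHH), its integral (iHH) and the
# cross-population statistic xp-EHH. EHH here is the unpolarized,
# whole-sample version used by xp-EHH: at distance x from the core,
# EHH(x) = sum_h C(n_h, 2) / C(n, 2) over groups of haplotypes identical
# between the core and x; EHH(core) = 1 by construction.

#' EHH profile from a core SNP outward
#'
#' @param h a `haplotypes` object (one population, one chromosome).
#' @param core_snp core SNP index or snp_id.
#' @param direction "left", "right" or "both".
#' @return data.frame(index, pos, ehh) ordered outward from the core
#'   (direction "both" returns the profile sorted by position, core
#'   included once).
#' @export
ehh <- function(h, core_snp, direction = c("both", "left", "right")) {
  direction <- match.arg(direction)
  if (is.character(core_snp)) core_snp <- match(core_snp, h$variants$snp_id)
  n <- nrow(h$haplos)
  if (n < 4L) ps_stop("ehh: needs >= 4 haplotypes")
  m <- ncol(h$haplos)
  if (is.na(core_snp) || core_snp < 1L || core_snp > m)
    ps_stop("ehh: core SNP outside chromosome")
  one_side <- function(idx_seq) {
    grp <- rep(1L, n)
    ehh_v <- numeric(length(idx_seq))
    for (k in seq_along(idx_seq)) {
      j <- idx_seq[k]
      if (j != core_snp) {
        key <- grp * 2L + h$haplos[, j]
        grp <- match(key, unique(key))
      }
      cnt <- tabulate(grp)
      ehh_v[k] <- sum(cnt * (cnt - 1)) / (n * (n - 1))
    }
    data.frame(index = idx_seq, pos = h$variants$pos[idx_seq], ehh = ehh_v)
  }
  left <- if (direction %in% c("left", "both")) one_side(core_snp:1L) else NULL
  right <- if (direction %in% c("right", "both")) one_side(core_snp:m) else NULL
  out <- switch(direction,
                left = left, right = right,
                both = rbind(left[rev(seq_len(nrow(left)))[-nrow(left)], ], right))
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' @noRd
ihh_one_side <- function(haplos, pos, core, step, ehh_min, max_gap_bp) {
  # integrate EHH from the core outward (step = +1 right, -1 left) until EHH
  # drops below ehh_min; returns NA if truncation never happens before the
  # chromosome end or an inter-marker gap exceeds max_gap_bp. Haplotypes
  # that become singletons never contribute to EHH again and are dropped,
  # which keeps the walk cheap.
  n <- nrow(haplos)
  m <- ncol(haplos)
  denom <- n * (n - 1)
  active <- seq_len(n)
  grp <- rep(1L, n)
  area <- 0
  prev_pos <- pos[core]; prev_e <- 1
  j <- core
  repeat {
    j <- j + step
    if (j < 1L || j > m) return(NA_real_)      # ran off the chromosome
    if (abs(pos[j] - prev_pos) > max_gap_bp) return(NA_real_)
    key <- grp * 2L + haplos[active, j]
    grp <- match(key, unique(key))
    cnt <- tabulate(grp)
    keep <- cnt[grp] > 1L
    if (!all(keep)) {
      active <- active[keep]
      grp <- match(grp[keep], unique(grp[keep]))
      cnt <- tabulate(grp)
    }
    e <- sum(cnt * (cnt - 1L)) / denom
    area <- area + abs(pos[j] - prev_pos) * (prev_e + e) / 2
    prev_pos <- pos[j]; prev_e <- e
    if (e < ehh_min) return(area)
  }
}

#' Integrated EHH (iHH) at a core SNP
#'
#' Trapezoidal integral of the EHH profile versus physical position,
#' truncated on each side at the first marker where EHH falls below
#' `ehh_min`.
#'
#' @param h a `haplotypes` object.
#' @param core_snp core index or snp_id.
#' @param ehh_min truncation level (default 0.05).
#' @param max_gap_bp cores whose integration span crosses a larger
#'   inter-marker gap are invalid (default 2e5).
#' @return iHH in base-pair units, or NA when truncation is impossible or a
#'   gap intervenes.
#' @export
ihh <- function(h, core_snp, ehh_min = 0.05, max_gap_bp = 2e5) {
  if (is.character(core_snp)) core_snp <- match(core_snp, h$variants$snp_id)
  pos <- as.numeric(h$variants$pos)
  l <- cpp_ihh_side(h$haplos, pos, core_snp, -1L, ehh_min, max_gap_bp)
  r <- cpp_ihh_side(h$haplos, pos, core_snp, +1L, ehh_min, max_gap_bp)
  l + r
}

#' Cross-population EHH (raw scores)
#'
#' `xpehh = ln(iHH_A / iHH_B)` at every usable core SNP; cores invalid in
#' either population (no truncation before the chromosome end, oversized
#' gap, or zero integral) are NA with the count reported via attribute
#' `n_excluded`.
#'
#' @param hap_a,hap_b `haplotypes` objects for the two populations on the
#'   same variant map.
#' @param ehh_min,max_gap_bp see [ihh()].
#' @param cores core SNP indices to score (default: every marker). EHH
#'   integration always walks the full marker map, so scoring a subset of
#'   cores does not change their values.
#' @return named numeric vector of raw scores (snp_id names), NA at
#'   unscored cores.
#' @export
xpehh <- function(hap_a, hap_b, ehh_min = 0.05, max_gap_bp = 2e5,
                  cores = NULL) {
  if (!identical(hap_a$variants$snp_id, hap_b$variants$snp_id))
    ps_stop("xpehh: the two populations must share one variant map")
  m <- ncol(hap_a$haplos)
  cores <- cores %||% seq_len(m)
  raw <- rep(NA_real_, m)
  for (j in cores) {
    ia <- ihh(hap_a, j, ehh_min, max_gap_bp)
    ib <- ihh(hap_b, j, ehh_min, max_gap_bp)
    if (is.na(ia) || is.na(ib) || ia <= 0 || ib <= 0) next
    raw[j] <- log(ia / ib)
  }
  names(raw) <- hap_a$variants$snp_id
  attr(raw, "n_excluded") <- sum(is.na(raw[cores]))
  raw
}

#' Genome-wide standardization of raw xp-EHH scores
#'
#' @param raw numeric vector of raw scores (NAs preserved).
#' @return z-scores with mean 0 and SD 1 over defined entries.
#' @export
standardize_xpehh <- function(raw) {
  ok <- !is.na(raw)
  if (sum(ok) < 2L) ps_stop("standardize_xpehh: needs >= 2 defined scores")
  s <- stats::sd(raw[ok])
  if (s == 0) ps_stop("standardize_xpehh: zero variance")
  out <- raw
  out[ok] <- (raw[ok] - mean(raw[ok])) / s
  out
}
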