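#' Nucleotide diversity of a haplotype group
#'
#' Average number of pairwise differences per base pair:
#' \eqn{\pi = \sum_{i<j} d_{ij} / \binom{k}{2} / L}, where `d_ij` counts
#' allele differences between haplotypes `i` and `j` over the alignment's
#' SNP sites and `L = span_bp` is the monomorphic-inclusive length of the
#' region the SNPs were ascertained in.
#'
#' @param aln A [hap_alignment()].
#' @param group Optional group label; restricts the calculation to
#'   haplotypes with that label.
#' @param span_bp Region length in bp; must be at least the number of SNP
#'   sites. Default: the positional span of the alignment's sites.
#' @return Scalar diversity per bp.
#' @export
nucleotide_diversity <- function(aln, group = NULL, span_bp = NULL) {
  h <- aln$haplotypes
  if (!is.null(group)) {
    if (is.null(aln$group)) abort("alignment has no group labels")
    h <- h[aln$group == group, , drop = FALSE]
  }
  k <- nrow(h)
  if (k < 2) abort("need >= 2 haplotypes")
  if (is.null(span_bp)) {
    span_bp <- diff(range(aln$sites$pos)) + 1L
  }
  if (span_bp < ncol(h)) abort("span_bp must be >= number of SNP sites")
  c1 <- colSums(h)  # alt-allele counts per site
  total_diffs <- sum(c1 * (k - c1))
  total_diffs / choose(k, 2) / span_bp
}

#' Haplotype frequencies from diagnostic markers
#'
#' At a structural variant segregating as two haplotype classes (e.g. the
#' northern N and southern S arrangements of an inversion), diagnostic
#' markers are sites nearly fixed for alternative alleles between two
#' reference pool groups: those with
#' `|mean f(S pools) - mean f(N pools)| >= diag_delta`. Each pool's
#' S-haplotype frequency is then the mean, across diagnostic markers, of its
#' frequency of the S-associated allele.
#'
#' @param freq Frequency table from [corrected_frequency()].
#' @param pools_s,pools_n Pool ids of the reference groups assumed near-fixed
#'   for the S and N haplotype respectively.
#' @param diag_delta Minimum between-group frequency difference for a
#'   diagnostic marker (default 0.8).
#' @param sites Optional tibble with `chrom`, `pos` restricting the search
#'   (e.g. the inversion span).
#' @return A tibble `pool_id`, `s_frequency`, `n_markers`; the diagnostic
#'   marker table (`chrom`, `pos`, `delta`, `s_allele`) is attached as the
#'   `diagnostics` attribute.
#' @export
haplotype_frequency <- function(freq, pools_s, pools_n, diag_delta = 0.8,
                                sites = NULL) {
  fm <- freq_matrix(freq, "f")
  if (!is.null(sites)) {
    keep <- site_key(fm$sites$chrom, fm$sites$pos) %in%
      site_key(sites$chrom, sites$pos)
    fm$m <- fm$m[keep, , drop = FALSE]
    fm$sites <- fm$sites[keep, , drop = FALSE]
  }
  missing_pools <- setdiff(c(pools_s, pools_n), fm$pools)
  if (length(missing_pools) > 0) {
    abort(paste0("reference pool(s) not in frequency table: ",
                 paste(missing_pools, collapse = ", ")))
  }
  m_s <- rowMeans(fm$m[, pools_s, drop = FALSE], na.rm = TRUE)
  m_n <- rowMeans(fm$m[, pools_n, drop = FALSE], na.rm = TRUE)
  delta <- m_s - m_n
  diag_idx <- which(!is.na(delta) & abs(delta) >= diag_delta)
  if (length(diag_idx) == 0) {
    abort(sprintf(
      "no diagnostic markers at delta >= %g; try a lower diag_delta",
      diag_delta))
  }
  s_is_alt <- delta[diag_idx] > 0
  fd <- fm$m[diag_idx, , drop = FALSE]
  fd[!s_is_alt, ] <- 1 - fd[!s_is_alt, ]  # orient toward the S allele
  out <- tibble(
    pool_id = fm$pools,
    s_frequency = unname(colMeans(fd, na.rm = TRUE)),
    n_markers = unname(colSums(!is.na(fd)))
  )
  attr(out, "diagnostics") <- tibble(
    chrom = fm$sites$chrom[diag_idx],
    pos = fm$sites$pos[diag_idx],
    delta = abs(delta[diag_idx]),
    s_allele = ifelse(s_is_alt, "alt", "ref")
  )
  out
}
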