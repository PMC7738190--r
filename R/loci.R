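#' Cluster significant SNPs into independent loci
#'
#' Significant SNPs (the scan's `significant` mask) on each chromosome are
#' merged by single linkage while consecutive inter-SNP gaps are smaller than
#' `merge_dist`, so reported loci are guaranteed at least `merge_dist` apart.
#' A merged cluster is reported as an independent locus only if (1) its span
#' (distance between its outermost member SNPs, inclusive) is at least
#' `min_span` base pairs and (2) at least two member SNPs reach
#' `p_raw < strong_p`. Locus boundaries are the member-SNP extremes, with no
#' padding.
#'
#' @param scan A `pool_scan` (or any tibble with `chrom`, `pos`, `p_raw`,
#'   `significant`).
#' @param min_span Minimum locus span in bp (default 100).
#' @param strong_p Raw-p threshold defining "strong" member SNPs (default
#'   `1e-20`).
#' @param merge_dist Minimum distance between independent loci in bp
#'   (default `1e5`); SNPs closer than this are merged.
#' @return A tibble of loci: `chrom`, `start`, `end`, `span`, `n_snps`,
#'   `n_strong`, `top_pos`, `top_p`, sorted by position.
#' @export
cluster_loci <- function(scan, min_span = 100, strong_p = 1e-20,
                         merge_dist = 1e5) {
  sig <- scan[scan$significant, c("chrom", "pos", "p_raw")]
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  span = integer(), n_snps = integer(), n_strong = integer(),
                  top_pos = integer(), top_p = double()))
  }
  sig <- arrange(as_tibble(sig), .data$chrom, .data$pos)
  sig <- sig |>
    group_by(.data$chrom) |>
    mutate(gap = .data$pos - dplyr::lag(.data$pos),
           new_cluster = is.na(.data$gap) | .data$gap >= merge_dist,
           cluster = cumsum(.data$new_cluster)) |>
    ungroup()
  loci <- sig |>
    group_by(.data$chrom, .data$cluster) |>
    summarise(
      start = min(.data$pos),
      end = max(.data$pos),
      span = max(.data$pos) - min(.data$pos) + 1L,
      n_snps = dplyr::n(),
      n_strong = sum(.data$p_raw < strong_p),
      top_pos = .data$pos[which.min(.data$p_raw)],
      top_p = min(.data$p_raw),
      .groups = "drop"
    ) |>
    filter(.data$span >= min_span, .data$n_strong >= 2) |>
    select(-"cluster") |>
    arrange(.data$chrom, .data$start)
  loci
}

#' Intersect loci and significant SNPs between two replicate contrasts
#'
#' Replicated selection signals are identified by overlapping the
#' independent loci of two scans over the same coordinate system (any >= 1 bp
#' interval overlap) and by intersecting the individual significant SNP
#' positions.
#'
#' @param loci_a,loci_b Locus tables from [cluster_loci()].
#' @param scan_a,scan_b Optional scans providing site-level significance
#'   masks; when both are given, shared significant SNPs are reported too.
#' @return A list with `loci` (tibble of overlapping pairs: `chrom`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, `overlap_bp`) and `snps`
#'   (tibble `chrom`, `pos` of SNPs significant in both scans, or `NULL`).
#' @export
intersect_contrasts <- function(loci_a, loci_b, scan_a = NULL, scan_b = NULL) {
  pairs <- inner_join(
    select(loci_a, "chrom", start_a = "start", end_a = "end"),
    select(loci_b, "chrom", start_b = "start", end_b = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter(.data$start_a <= .data$end_b, .data$start_b <= .data$end_a) |>
    mutate(overlap_bp = pmin(.data$end_a, .data$end_b) -
             pmax(.data$start_a, .data$start_b) + 1L)
  snps <- NULL
  if (!is.null(scan_a) && !is.null(scan_b)) {
    snps <- inner_join(
      as_tibble(scan_a)[scan_a$significant, c("chrom", "pos")],
      as_tibble(scan_b)[scan_b$significant, c("chrom", "pos")],
      by = c("chrom", "pos")
    )
  }
  list(loci = pairs, snps = snps)
}
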