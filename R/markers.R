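#' Partition markers into undifferentiated and highly differentiated sets
#'
#' Sites first pass a minor-allele-frequency filter
#' (`min(mean_f, 1 - mean_f) > maf_min`, excluding monomorphic sites and rare
#' variants), then are classified by the across-pool standard deviation of
#' allele frequency: `std_low[1] <= std <= std_low[2]` marks an
#' undifferentiated marker, `std >= std_high` a highly differentiated one.
#' Sites between the two bands (or below the lower band) belong to neither
#' set.
#'
#' @param site_stats Per-site table from [frequency_std()] (columns `mean_f`,
#'   `sd_f`).
#' @param std_low Length-2 numeric, inclusive std band for undifferentiated
#'   markers. Default `c(0.02, 0.08)`.
#' @param std_high Lower std bound (inclusive) for highly differentiated
#'   markers. Default `0.2`.
#' @param maf_min Minor allele frequency must exceed this value. Default
#'   `0.01`.
#' @return `site_stats` with added columns `maf` and `marker_class` (factor
#'   with levels `"undifferentiated"`, `"differentiated"`; `NA` for
#'   unclassified sites). Thresholds are stored in the `thresholds`
#'   attribute.
#' @export
partition_markers <- function(site_stats, std_low = c(0.02, 0.08),
                              std_high = 0.2, maf_min = 0.01) {
  stopifnot(length(std_low) == 2, std_low[1] <= std_low[2],
            std_low[2] < std_high)
  maf <- pmin(site_stats$mean_f, 1 - site_stats$mean_f)
  std <- site_stats$sd_f
  pass_maf <- !is.na(maf) & maf > maf_min & !is.na(std)
  cls <- rep(NA_character_, nrow(site_stats))
  cls[pass_maf & std >= std_low[1] & std <= std_low[2]] <- "undifferentiated"
  cls[pass_maf & std >= std_high] <- "differentiated"
  out <- mutate(site_stats, maf = maf,
                marker_class = factor(cls, levels = c("undifferentiated",
                                                      "differentiated")))
  attr(out, "thresholds") <- list(std_low = std_low, std_high = std_high,
                                  maf_min = maf_min)
  out
}

#' Thin markers to one per genomic window
#'
#' Linked markers up- or down-weight genomic regions in PCA, so each marker
#' set is down-sampled to a single site per fixed window. Chromosomes are
#' tiled into non-overlapping windows `[1, w]`, `[w + 1, 2w]`, ... anchored
#' at position 1, and the lowest-position site in each window is retained.
#' Conventional window sizes are 1 kb for undifferentiated and 10 kb for
#' highly differentiated markers.
#'
#' @param sites Tibble with columns `chrom` and `pos`, sorted by
#'   `(chrom, pos)`.
#' @param window_bp Window size in base pairs.
#' @return The retained rows of `sites`.
#' @export
thin_markers <- function(sites, window_bp) {
  stopifnot(window_bp >= 1)
  if (nrow(sites) == 0) return(sites)
  sorted <- !is.unsorted(order(sites$chrom, sites$pos)) &&
    all(order(sites$chrom, sites$pos) == seq_len(nrow(sites)))
  if (!sorted) abort("sites must be sorted by (chrom, pos)")
  sites |>
    group_by(.data$chrom, window = (.data$pos - 1) %/% window_bp) |>
    dplyr::slice_min(.data$pos, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-"window") |>
    arrange(.data$chrom, .data$pos)
}
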