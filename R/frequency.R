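#' Effective allele count for pooled sequencing
#'
#' Pool-seq allele frequencies are doubly sampled: once when `n` diploid
#' individuals are drawn from the population (2n chromosomes) and once when
#' reads are drawn from the pool. The effective number of chromosomes
#'
#' \deqn{N_{eff} = \frac{2n \cdot RD - 1}{2n + RD}}
#'
#' is the count that carries the equivalent information of a single-stage
#' sample; it is bounded above by both `2n` and `RD` and approaches `2n` as
#' read depth grows. Values are returned un-rounded.
#'
#' @param n Number of diploid individuals in the pool (vectorised).
#' @param rd Raw read depth at the site (vectorised). `rd = 0` yields `NA`
#'   (missing data).
#' @return Numeric vector of effective allele counts.
#' @examples
#' effective_count(50, 100)  # 49.995
#' @export
effective_count <- function(n, rd) {
  if (any(n < 1)) abort("n must be >= 1")
  if (any(rd < 0)) abort("rd must be non-negative")
  out <- (2 * n * rd - 1) / (2 * n + rd)
  out[rd == 0] <- NA_real_
  out
}

#' N_eff-corrected allele frequencies per pool and site
#'
#' Computes the alternate-allele frequency `f = alt_count / RD` for every
#' pool x site cell with reads, together with the effective allele count
#' `N_eff` (see [effective_count()]) and the corrected fractional allele
#' counts `f * N_eff` and `(1 - f) * N_eff`. Cells with zero depth are
#' missing (`NA`), never zero. The correction rescales counts, not the
#' frequency itself.
#'
#' @param counts Long counts tibble (see [read_sync()]).
#' @param metadata Pool metadata with `pool_id` and `n_individuals`; every
#'   pool present in `counts` must be described.
#' @return A tibble with columns `chrom`, `pos`, `pool_id`, `rd`, `f`,
#'   `n_eff`, `alt_corrected`, `ref_corrected`.
#' @export
corrected_frequency <- function(counts, metadata) {
  check_counts(counts)
  check_metadata(metadata)
  missing_pools <- setdiff(unique(counts$pool_id), metadata$pool_id)
  if (length(missing_pools) > 0) {
    abort(paste0("pool(s) present in counts but absent from metadata: ",
                 paste(missing_pools, collapse = ", ")))
  }
  n <- metadata$n_individuals[match(counts$pool_id, metadata$pool_id)]
  rd <- counts$ref_count + counts$alt_count
  f <- ifelse(rd > 0, counts$alt_count / rd, NA_real_)
  n_eff <- effective_count(n, rd)
  tibble(
    chrom = counts$chrom,
    pos = counts$pos,
    pool_id = counts$pool_id,
    rd = rd,
    f = f,
    n_eff = n_eff,
    alt_corrected = f * n_eff,
    ref_corrected = (1 - f) * n_eff
  )
}

#' Per-site spread of allele frequencies across pools
#'
#' The genome-wide distribution of the per-site standard deviation (std) of
#' allele frequencies across population pools is the basis for partitioning
#' markers into undifferentiated and highly differentiated sets (see
#' [partition_markers()]). Uses the sample standard deviation (denominator
#' `N - 1`); missing cells are excluded, and a site needs at least two
#' informative pools for a defined std.
#'
#' @param freq Frequency table from [corrected_frequency()].
#' @param pools Optional character vector restricting the calculation to a
#'   pool subset (e.g. the pools entering one contrast).
#' @return A tibble with columns `chrom`, `pos`, `n_informative`, `mean_f`,
#'   `sd_f`.
#' @export
frequency_std <- function(freq, pools = NULL) {
  fm <- freq_matrix(freq, "f", pools = pools)
  tibble(
    chrom = fm$sites$chrom,
    pos = fm$sites$pos,
    n_informative = rowSums(!is.na(fm$m)),
    mean_f = rowMeans(fm$m, na.rm = TRUE),
    sd_f = row_sd(fm$m)
  )
}
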