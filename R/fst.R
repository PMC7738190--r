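#' Per-SNP F_ST between two pools from read counts
#'
#' Nucleotide-diversity-based estimator with a finite-depth correction, the
#' classical definition used for pooled sliding-window F_ST: within-pool
#' heterozygosity \eqn{\pi_k = \frac{RD_k}{RD_k - 1} 2 f_k (1 - f_k)},
#' \eqn{\pi_S} the mean of the two pools, \eqn{\pi_T} the same quantity on
#' the summed counts, and \eqn{F_{ST} = (\pi_T - \pi_S)/\pi_T}. Sites with
#' depth below 2 in either pool, or with \eqn{\pi_T = 0}, are undefined
#' (`NA`). As depth grows the estimator converges to the frequency-only
#' classical value.
#'
#' When pool sizes are supplied, the correction factors use the effective
#' allele count [effective_count()] in place of raw depth, acknowledging
#' that a pool of `n` individuals carries at most `2n` chromosomes; by
#' default raw depth is used.
#'
#' @param ref_a,alt_a,ref_b,alt_b Read counts (vectorised over sites).
#' @param n_a,n_b Optional pool sizes (diploid individuals) enabling the
#'   N_eff-based correction.
#' @return Numeric vector of per-site F_ST (may be negative at finite
#'   depth).
#' @export
site_fst <- function(ref_a, alt_a, ref_b, alt_b, n_a = NULL, n_b = NULL) {
  rd_a <- ref_a + alt_a
  rd_b <- ref_b + alt_b
  f_a <- alt_a / rd_a
  f_b <- alt_b / rd_b
  d_a <- if (is.null(n_a)) rd_a else effective_count(n_a, rd_a)
  d_b <- if (is.null(n_b)) rd_b else effective_count(n_b, rd_b)
  d_t <- d_a + d_b
  pi_a <- d_a / (d_a - 1) * 2 * f_a * (1 - f_a)
  pi_b <- d_b / (d_b - 1) * 2 * f_b * (1 - f_b)
  pi_s <- (pi_a + pi_b) / 2
  f_t <- (alt_a + alt_b) / (rd_a + rd_b)
  pi_t <- d_t / (d_t - 1) * 2 * f_t * (1 - f_t)
  fst <- (pi_t - pi_s) / pi_t
  fst[rd_a < 2 | rd_b < 2 | pi_t == 0] <- NA_real_
  fst
}

#' Pairwise F_ST between two pools in sliding windows
#'
#' Sites are filtered like the standard pooled sliding-window pipeline: the
#' minor allele count summed over both pools must reach `min_count`, and each
#' pool's depth must lie in `[min_cov, max_cov]`. Chromosomes are tiled with
#' windows of `window` bp starting at position 1 every `step` bp; a window's
#' value is the plain mean of qualifying per-site F_ST estimates (negative
#' site estimates retained), with the reported `fst` floored at 0 and the
#' raw mean kept in `fst_raw`. `covered_fraction` is the share of the
#' window's SNP sites that qualify; windows below `min_cov_frac` or with no
#' qualifying site have `fst = NA`. Windows containing no SNPs at all are
#' omitted.
#'
#' @param counts Long counts tibble.
#' @param pool_a,pool_b Pool ids.
#' @param window,step Window and step size in bp (defaults 5000/5000).
#' @param min_count Minimum summed minor-allele count (default 10).
#' @param min_cov,max_cov Per-pool depth bounds (defaults 10 and 500).
#' @param min_cov_frac Minimum covered fraction (default 0.7).
#' @param n_a,n_b Optional pool sizes passed to [site_fst()].
#' @return A tibble: `chrom`, `start`, `end`, `fst`, `fst_raw`,
#'   `n_snps_used`, `n_snps_total`, `covered_fraction`.
#' @export
sliding_fst <- function(counts, pool_a, pool_b, window = 5000, step = 5000,
                        min_count = 10, min_cov = 10, max_cov = 500,
                        min_cov_frac = 0.7, n_a = NULL, n_b = NULL) {
  if (window <= 0 || step <= 0) abort("window and step must be positive")
  pair <- site_pair_counts(counts, pool_a, pool_b)
  q <- pair_site_filter(pair, min_count, min_cov, max_cov)
  fst <- site_fst(pair$ref_a, pair$alt_a, pair$ref_b, pair$alt_b, n_a, n_b)
  q <- q & !is.na(fst)

  out <- lapply(split(seq_len(nrow(pair)), pair$chrom), function(idx) {
    pos <- pair$pos[idx]                      # sorted within chromosome
    starts <- seq(1, max(pos), by = step)
    ends <- starts + window - 1
    lo <- findInterval(starts - 0.5, pos) + 1L
    hi <- findInterval(ends + 0.5, pos)
    n_total <- hi - lo + 1L
    keep <- n_total > 0
    cq <- cumsum(c(0, q[idx]))
    cf <- cumsum(c(0, ifelse(q[idx], fst[idx], 0)))
    n_used <- (cq[hi + 1L] - cq[lo])[keep]
    sum_fst <- (cf[hi + 1L] - cf[lo])[keep]
    tibble(
      chrom = pair$chrom[idx[1]],
      start = as.integer(starts[keep]),
      end = as.integer(ends[keep]),
      n_snps_used = as.integer(n_used),
      n_snps_total = n_total[keep],
      fst_raw = ifelse(n_used > 0, sum_fst / n_used, NA_real_),
      covered_fraction = n_used / n_total[keep]
    )
  })
  res <- bind_rows(out) |>
    mutate(fst = ifelse(!is.na(.data$fst_raw) &
                          .data$covered_fraction >= min_cov_frac,
                        pmax(.data$fst_raw, 0), NA_real_)) |>
    select("chrom", "start", "end", "fst", "fst_raw", "n_snps_used",
           "n_snps_total", "covered_fraction") |>
    arrange(.data$chrom, .data$start)
  res
}

#' Genome-wide pairwise F_ST matrix across pools
#'
#' For every pool pair, the genome-wide mean of qualifying per-site F_ST
#' estimates (same site filters as [sliding_fst()], no windowing), floored
#' at 0 as for windows. The result is symmetric with a zero diagonal.
#'
#' @inheritParams sliding_fst
#' @param metadata Pool metadata; its `pool_id` order defines the matrix
#'   order, and `n_individuals` feeds the optional N_eff correction when
#'   `use_n_eff = TRUE`.
#' @param use_n_eff Use effective allele counts in the correction factors
#'   (default `FALSE`, raw depth).
#' @return A pools x pools numeric matrix.
#' @export
pairwise_fst_matrix <- function(counts, metadata, min_count = 10,
                                min_cov = 10, max_cov = 500,
                                use_n_eff = FALSE) {
  check_metadata(metadata)
  pools <- metadata$pool_id
  if (length(pools) < 2) abort("need >= 2 pools")
  cm <- count_matrices(counts, pools = pools)
  mat <- matrix(0, length(pools), length(pools),
                dimnames = list(pools, pools))
  for (i in seq_along(pools)[-length(pools)]) {
    for (j in seq((i + 1), length(pools))) {
      ref_a <- cm$ref[, i]; alt_a <- cm$alt[, i]
      ref_b <- cm$ref[, j]; alt_b <- cm$alt[, j]
      rd_a <- ref_a + alt_a; rd_b <- ref_b + alt_b
      minor <- pmin(ref_a + ref_b, alt_a + alt_b)
      ok <- minor >= min_count & rd_a >= min_cov & rd_a <= max_cov &
        rd_b >= min_cov & rd_b <= max_cov
      n_a <- if (use_n_eff) metadata$n_individuals[i] else NULL
      n_b <- if (use_n_eff) metadata$n_individuals[j] else NULL
      fst <- site_fst(ref_a[ok], alt_a[ok], ref_b[ok], alt_b[ok], n_a, n_b)
      mat[i, j] <- mat[j, i] <- max(0, mean(fst, na.rm = TRUE))
    }
  }
  mat
}

# Align two pools' counts on shared sites, sorted by (chrom, pos).
site_pair_counts <- function(counts, pool_a, pool_b) {
  present <- unique(counts$pool_id)
  unknown <- setdiff(c(pool_a, pool_b), present)
  if (length(unknown) > 0) {
    abort(paste0("pool(s) not present in counts: ",
                 paste(unknown, collapse = ", ")))
  }
  cm <- count_matrices(counts, pools = c(pool_a, pool_b))
  tibble(
    chrom = cm$sites$chrom, pos = cm$sites$pos,
    ref_a = cm$ref[, 1], alt_a = cm$alt[, 1],
    ref_b = cm$ref[, 2], alt_b = cm$alt[, 2]
  )
}

pair_site_filter <- function(pair, min_count, min_cov, max_cov) {
  rd_a <- pair$ref_a + pair$alt_a
  rd_b <- pair$ref_b + pair$alt_b
  minor <- pmin(pair$ref_a + pair$ref_b, pair$alt_a + pair$alt_b)
  minor >= min_count & rd_a >= min_cov & rd_a <= max_cov &
    rd_b >= min_cov & rd_b <= max_cov
}
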