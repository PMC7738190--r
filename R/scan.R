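#' Sum read counts into superpool 2x2 tables
#'
#' Populations are grouped into two superpools according to an environmental
#' variable or phenotype, and read counts are summed separately for the
#' reference and alternate allele within each superpool, giving one 2x2
#' contingency table per SNP. Sites where either superpool has zero total
#' depth are excluded (count kept in the `n_excluded` attribute).
#'
#' @param counts Long counts tibble (see [read_sync()]).
#' @param pools_a,pools_b Character vectors of pool ids forming the two
#'   superpools; must be disjoint, non-empty, and present in `counts`.
#' @return A tibble with one row per retained site: `chrom`, `pos`, `ref`,
#'   `alt`, `ref_a`, `alt_a`, `ref_b`, `alt_b`.
#' @export
superpool_tables <- function(counts, pools_a, pools_b) {
  if (length(pools_a) == 0 || length(pools_b) == 0) {
    abort("both superpools must be non-empty")
  }
  if (length(intersect(pools_a, pools_b)) > 0) {
    abort("superpools must be disjoint")
  }
  present <- unique(counts$pool_id)
  unknown <- setdiff(c(pools_a, pools_b), present)
  if (length(unknown) > 0) {
    abort(paste0("pool(s) not present in counts: ",
                 paste(unknown, collapse = ", ")))
  }
  cm <- count_matrices(counts)
  a <- match(pools_a, cm$pools)
  b <- match(pools_b, cm$pools)
  out <- tibble(
    chrom = cm$sites$chrom,
    pos = cm$sites$pos,
    ref = cm$sites$ref,
    alt = cm$sites$alt,
    ref_a = rowSums(cm$ref[, a, drop = FALSE]),
    alt_a = rowSums(cm$alt[, a, drop = FALSE]),
    ref_b = rowSums(cm$ref[, b, drop = FALSE]),
    alt_b = rowSums(cm$alt[, b, drop = FALSE])
  )
  empty <- (out$ref_a + out$alt_a == 0) | (out$ref_b + out$alt_b == 0)
  res <- out[!empty, , drop = FALSE]
  attr(res, "n_excluded") <- sum(empty)
  res
}

#' Per-SNP 2x2 chi-square test between superpools
#'
#' Pearson's chi-square statistic (1 df, no continuity correction) on each
#' site's summed read-count table, with the raw upper-tail p-value and the
#' absolute allele-frequency difference between superpools
#' `dAF = |alt_a/RD_a - alt_b/RD_b|`. Sites with a zero column marginal
#' (monomorphic across both superpools) have an undefined statistic and are
#' dropped (count in the `n_skipped` attribute).
#'
#' @param tables Superpool tables from [superpool_tables()].
#' @return `tables` with added columns `chi2`, `p_raw`, `d_af`.
#' @export
chi2_scan <- function(tables) {
  # doubles throughout: marginal products overflow integer range
  rd_a <- as.numeric(tables$ref_a) + as.numeric(tables$alt_a)
  rd_b <- as.numeric(tables$ref_b) + as.numeric(tables$alt_b)
  ref_t <- as.numeric(tables$ref_a) + as.numeric(tables$ref_b)
  alt_t <- as.numeric(tables$alt_a) + as.numeric(tables$alt_b)
  bad <- rd_a == 0 | rd_b == 0 | ref_t == 0 | alt_t == 0
  if (any(bad)) {
    inform(sprintf("chi2_scan: skipped %d site(s) with a zero marginal",
                   sum(bad)))
  }
  t2 <- tables[!bad, , drop = FALSE]
  rd_a <- rd_a[!bad]; rd_b <- rd_b[!bad]
  ref_t <- ref_t[!bad]; alt_t <- alt_t[!bad]
  n <- rd_a + rd_b
  chi2 <- n * (as.numeric(t2$ref_a) * t2$alt_b -
                 as.numeric(t2$alt_a) * t2$ref_b)^2 /
    (rd_a * rd_b * ref_t * alt_t)
  out <- mutate(t2,
                chi2 = chi2,
                p_raw = pchisq(chi2, df = 1, lower.tail = FALSE),
                d_af = abs(t2$alt_a / rd_a - t2$alt_b / rd_b))
  attr(out, "n_skipped") <- sum(bad)
  out
}

# Median of the chi-square distribution with 1 df.
CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

#' Genomic inflation factor
#'
#' `median(chi2) / 0.4549364`, the ratio of the observed median statistic to
#' the null median of a 1-df chi-square.
#'
#' @param chi2 Vector of 1-df chi-square statistics.
#' @param clamp If `TRUE`, never return less than 1 (deflation is not
#'   corrected).
#' @return Scalar lambda.
#' @export
inflation_factor <- function(chi2, clamp = FALSE) {
  lambda <- median(chi2, na.rm = TRUE) / CHISQ1_MEDIAN
  if (clamp) lambda <- max(lambda, 1)
  lambda
}

#' Genomic-control correction and significance thresholding of a scan
#'
#' Superpool contrasts built from structured populations inflate the
#' chi-square statistics above their null distribution (baseline
#' differentiation acts like overdispersion). The genomic inflation factor
#' lambda is estimated by median-based genomic control
#' ([inflation_factor()], clamped below at 1), every statistic is divided by
#' lambda, and p-values are recomputed from the adjusted statistic. A
#' Bonferroni correction over the `m` tested sites is then applied, and
#' sites with adjusted p below `threshold` are flagged significant.
#'
#' @param scan Output of [chi2_scan()].
#' @param threshold Significance threshold on the adjusted p-value
#'   (default `1e-10`).
#' @param adjust Which corrections define the reported adjusted p-value:
#'   `"both"` (lambda then Bonferroni, the default), `"lambda"` only, or
#'   `"bonferroni"` only (on raw p).
#' @param min_sites Minimum number of tested sites for a stable lambda
#'   estimate (default 1000); fewer is an error advising use of raw
#'   p-values.
#' @return A `pool_scan` object: the per-site tibble with added columns
#'   `chi2_adj`, `p_lambda`, `p_adj`, `significant`, and attributes
#'   `lambda`, `m`, `threshold`, `adjust`.
#' @seealso [glance.pool_scan()]
#' @export
genomic_control <- function(scan, threshold = 1e-10,
                            adjust = c("both", "lambda", "bonferroni"),
                            min_sites = 1000) {
  adjust <- match.arg(adjust)
  m <- nrow(scan)
  if (m < min_sites) {
    abort(sprintf(
      "only %d tested sites; lambda estimation needs >= %d. Use raw p-values.",
      m, min_sites))
  }
  lambda <- inflation_factor(scan$chi2, clamp = TRUE)
  chi2_adj <- scan$chi2 / lambda
  p_lambda <- pchisq(chi2_adj, df = 1, lower.tail = FALSE)
  p_adj <- switch(adjust,
    both = pmin(1, m * p_lambda),
    lambda = p_lambda,
    bonferroni = pmin(1, m * scan$p_raw)
  )
  out <- mutate(scan,
                chi2_adj = chi2_adj,
                p_lambda = p_lambda,
                p_adj = p_adj,
                significant = p_adj < threshold)
  attr(out, "lambda") <- lambda
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  attr(out, "adjust") <- adjust
  class(out) <- c("pool_scan", class(out))
  out
}

#' @method glance pool_scan
#' @export
glance.pool_scan <- function(x, ...) {
  tibble(
    lambda = attr(x, "lambda"),
    m = attr(x, "m"),
    n_significant = sum(x$significant),
    threshold = attr(x, "threshold"),
    adjust = attr(x, "adjust")
  )
}

#' @method tidy pool_scan
#' @export
tidy.pool_scan <- function(x, ...) {
  as_tibble(x)
}
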