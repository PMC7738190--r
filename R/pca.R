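#' Principal component analysis of pools on corrected allele frequencies
#'
#' Pools are observations, markers variables. Markers are mean-centered
#' across pools but not variance-scaled (frequencies already share a scale;
#' scaling would up-weight near-monomorphic sites); missing cells are imputed
#' to the marker mean, which is neutral for centered PCA. Scores come from
#' the singular value decomposition, and the variance explained by each
#' component is its squared singular value over the total. Each component is
#' oriented so that its largest-magnitude loading is positive.
#'
#' @param freq Frequency table from [corrected_frequency()].
#' @param sites Optional tibble with `chrom`, `pos` selecting the marker set
#'   (e.g. a thinned partition class); default uses all sites.
#' @param k Number of components to keep; clamped (with a warning) to
#'   `min(n_pools, n_markers) - 1`.
#' @return An object of class `pool_pca`: list with `scores` (tibble,
#'   `pool_id` + `PC1..PCk`), `var_explained` (fraction per kept component),
#'   `loadings` (markers x components matrix), `sites`, `n_pools`,
#'   `n_markers`.
#' @seealso [tidy.pool_pca()], [autoplot.pool_pca()]
#' @export
pca_pools <- function(freq, sites = NULL, k = 10) {
  fm <- freq_matrix(freq, "f")
  if (!is.null(sites)) {
    keep <- site_key(fm$sites$chrom, fm$sites$pos) %in%
      site_key(sites$chrom, sites$pos)
    fm$m <- fm$m[keep, , drop = FALSE]
    fm$sites <- fm$sites[keep, , drop = FALSE]
  }
  x <- t(fm$m)  # pools x markers
  if (nrow(x) < 2 || ncol(x) < 2) abort("PCA needs >= 2 pools and >= 2 markers")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, colMeans(x))
  max_k <- min(dim(x)) - 1L
  if (k > max_k) {
    warn(sprintf("k = %d exceeds the available rank; clamped to %d", k, max_k))
    k <- max_k
  }
  s <- svd(x)
  ve_all <- s$d^2 / sum(s$d^2)
  # orient each component so its largest-magnitude loading is positive
  flip <- vapply(seq_len(k), function(i) {
    v <- s$v[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(s$u[, seq_len(k), drop = FALSE] %*%
                    diag(s$d[seq_len(k)], k, k), 2, flip, `*`)
  loadings <- sweep(s$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = dplyr::bind_cols(tibble(pool_id = fm$pools),
                                as_tibble(scores)),
      var_explained = ve_all[seq_len(k)],
      loadings = loadings,
      sites = fm$sites,
      n_pools = nrow(x),
      n_markers = ncol(x)
    ),
    class = "pool_pca"
  )
}

#' @export
print.pool_pca <- function(x, ...) {
  cat(sprintf("<pool_pca> %d pools x %d markers, %d components\n",
              x$n_pools, x$n_markers, length(x$var_explained)))
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette of a grouping on PC scores
#'
#' Measures how well a pool grouping (e.g. superpool membership) is separated
#' in principal-component space: the mean silhouette width over pools,
#' computed on Euclidean distances between the first `n_components` score
#' vectors. Values near 1 mean clean separation, values near 0 (or negative)
#' none.
#'
#' @param pca A `pool_pca` object.
#' @param groups Named character vector (names = pool ids) or a tibble with
#'   `pool_id` and `group` columns.
#' @param n_components Number of leading components to use (default 2).
#' @return Mean silhouette width (scalar).
#' @export
pca_silhouette <- function(pca, groups, n_components = 2) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$pool_id)
  }
  g <- groups[pca$scores$pool_id]
  if (anyNA(g)) abort("every pool needs a group label")
  if (length(unique(g)) < 2) abort("need >= 2 groups")
  n_components <- min(n_components, length(pca$var_explained))
  m <- as.matrix(pca$scores[, paste0("PC", seq_len(n_components))])
  sil <- cluster::silhouette(as.integer(factor(g)), stats::dist(m))
  mean(sil[, "sil_width"])
}
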