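#' Plot pool PCA scores
#'
#' Scatter of the first two principal components with the percentage of
#' variance explained on the axes, optionally coloured by a pool grouping.
#'
#' @param object A `pool_pca`.
#' @param groups Optional named character vector (names = pool ids) or
#'   tibble with `pool_id` and `group`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pool_pca
#' @export
autoplot.pool_pca <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) {
    if (is.data.frame(groups)) groups <- setNames(groups$group, groups$pool_id)
    df$group <- groups[df$pool_id]
  }
  ve <- 100 * object$var_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ve[1]),
      y = sprintf("PC2 (%.1f%%)", ve[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
}

#' Manhattan plot of a superpool scan
#'
#' Per-site `-log10` adjusted p-values along the genome, faceted by
#' chromosome, with the scan's significance threshold drawn as a dashed
#' line.
#'
#' @param scan A `pool_scan` from [genomic_control()].
#' @param p_col Which p-value column to draw (default `"p_adj"`).
#' @return A ggplot.
#' @export
plot_manhattan <- function(scan, p_col = "p_adj") {
  df <- as_tibble(scan)
  df$logp <- -log10(pmax(df[[p_col]], 1e-300))
  thr <- attr(scan, "threshold")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$logp)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed")
  }
  p
}

#' Plot sliding-window F_ST along the genome
#'
#' @param windows Window table from [sliding_fst()].
#' @return A ggplot.
#' @export
plot_fst_windows <- function(windows) {
  df <- filter(windows, !is.na(.data$fst))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2 / 1e6,
                                   y = .data$fst)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(italic(F)[ST])) +
    ggplot2::theme_minimal()
}

#' Plot per-pool S-haplotype frequencies
#'
#' @param hf Output of [haplotype_frequency()].
#' @return A ggplot.
#' @export
plot_haplotype_frequency <- function(hf) {
  ggplot2::ggplot(hf, ggplot2::aes(x = .data$pool_id, y = .data$s_frequency)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "S-haplotype frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method tidy pool_pca
#' @export
tidy.pool_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"pool_id",
                                 names_to = "component",
                                 values_to = "score"),
    loadings = {
      df <- dplyr::bind_cols(x$sites, as_tibble(x$loadings))
      tidyr::pivot_longer(df, dplyr::starts_with("PC"),
                          names_to = "component", values_to = "loading")
    },
    eigenvalues = tibble(
      component = paste0("PC", seq_along(x$var_explained)),
      var_explained = x$var_explained
    )
  )
}

#' @method glance pool_pca
#' @export
glance.pool_pca <- function(x, ...) {
  tibble(n_pools = x$n_pools, n_markers = x$n_markers,
         k = length(x$var_explained),
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2]
                   else NA_real_)
}
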