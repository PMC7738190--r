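#' Nei's standard genetic distance between pools
#'
#' Nei (1972) standard distance on biallelic allele frequencies, computed
#' over all loci jointly (ratio of summed gene identities, not a per-locus
#' average). With `x`, `y` the alternate-allele frequency vectors of two
#' pools over their shared (both non-missing) sites,
#' \eqn{J_{XY} = \sum xy + (1-x)(1-y)}, \eqn{J_X = \sum x^2 + (1-x)^2},
#' \eqn{J_Y} likewise, the normalized identity is
#' \eqn{I = J_{XY} / \sqrt{J_X J_Y}} and \eqn{D = -\ln I}. An identity of 0
#' is capped at `max_distance` with a warning; an identity exceeding 1
#' beyond numerical tolerance is an error.
#'
#' @param freq Frequency table from [corrected_frequency()].
#' @param sites Optional tibble with `chrom`, `pos` restricting the site
#'   set.
#' @param pools Optional pool subset (default: all pools in `freq`).
#' @param max_distance Cap for infinite distances (default 50).
#' @return A symmetric pools x pools distance matrix with zero diagonal.
#' @export
nei_distance <- function(freq, sites = NULL, pools = NULL, max_distance = 50) {
  fm <- freq_matrix(freq, "f", pools = pools)
  if (!is.null(sites)) {
    keep <- site_key(fm$sites$chrom, fm$sites$pos) %in%
      site_key(sites$chrom, sites$pos)
    fm$m <- fm$m[keep, , drop = FALSE]
  }
  if (length(fm$pools) < 2) abort("need >= 2 pools")
  nei_distance_matrix(fm$m, labels = fm$pools, max_distance = max_distance)
}

# Core Nei distance on a sites x pools frequency matrix (NA = missing).
nei_distance_matrix <- function(f, labels = colnames(f), max_distance = 50) {
  obs <- !is.na(f)
  if (!any(colSums(obs) > 0)) abort("no informative sites")
  f0 <- ifelse(obs, f, 0)
  a <- f0                      # alt-allele frequency, 0 where missing
  b <- ifelse(obs, 1 - f0, 0)  # ref-allele frequency, 0 where missing
  j_cross <- crossprod(a) + crossprod(b)          # J_XY over shared sites
  s <- a^2 + b^2                                  # per-site self identity
  j_self <- crossprod(s, obs)                     # J_X restricted to pair
  n_shared <- crossprod(obs)
  if (any(n_shared[upper.tri(n_shared)] == 0)) {
    abort("some pool pairs share no informative site")
  }
  identity <- j_cross / sqrt(j_self * t(j_self))
  tol <- 1e-8
  if (any(identity > 1 + tol)) abort("normalized identity exceeds 1: non-frequency input?")
  identity <- pmin(identity, 1)
  d <- -log(identity)
  if (any(!is.finite(d))) {
    warn(sprintf("Nei identity of 0 for %d pair(s); distance capped at %g",
                 sum(!is.finite(d) & upper.tri(d)), max_distance))
    d[!is.finite(d)] <- max_distance
  }
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with negative branch
#' lengths floored at zero and the deficit transferred to the sister branch,
#' so leaf-to-leaf path lengths are preserved where possible.
#'
#' @param d Symmetric distance matrix (labels in dimnames) or `dist`.
#' @return An unrooted `phylo` tree.
#' @export
nj_pool_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  if (nrow(d) < 3) abort("neighbor joining needs >= 3 labels")
  tree <- ape::nj(stats::as.dist(d))
  fix_negative_edges(tree)
}

# Floor negative branch lengths at 0, transferring each deficit to the
# sister edge (the other edge sharing the same parent node).
fix_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sisters) > 0) {
      s <- sisters[1]
      tree$edge.length[s] <- tree$edge.length[s] + deficit
      if (tree$edge.length[s] < 0) tree$edge.length[s] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap majority-rule consensus tree over resampled sites
#'
#' SNP columns are resampled uniformly with replacement (same number of
#' sites as the original set) `n_reps` times; each replicate yields a Nei
#' distance matrix and a neighbor-joining tree. The majority-rule consensus
#' keeps clades present in more than half of the replicate trees, and each
#' retained clade is annotated with its support as a percentage
#' (node labels). Deterministic for a fixed `seed`.
#'
#' @inheritParams nei_distance
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @return A `phylo` consensus tree; internal `node.label` holds percentage
#'   supports.
#' @export
bootstrap_consensus <- function(freq, sites = NULL, pools = NULL,
                                n_reps = 1000, seed = 1,
                                max_distance = 50) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  fm <- freq_matrix(freq, "f", pools = pools)
  if (!is.null(sites)) {
    keep <- site_key(fm$sites$chrom, fm$sites$pos) %in%
      site_key(sites$chrom, sites$pos)
    fm$m <- fm$m[keep, , drop = FALSE]
  }
  n_sites <- nrow(fm$m)
  if (n_sites < 4) abort("bootstrap needs >= 4 sites")
  set.seed(seed)
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    d <- nei_distance_matrix(fm$m[idx, , drop = FALSE], labels = fm$pools,
                             max_distance = max_distance)
    trees[[r]] <- nj_pool_tree(d)
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- round(100 * counts / n_reps, 1)
  cons
}
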