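# Shared fixtures and independent oracles for the test suite.

# Random small long-format counts table.
random_counts <- function(n_sites = 20, n_pools = 3, seed = 1,
                          max_depth = 40) {
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  pools <- sprintf("P%d", seq_len(n_pools))
  rd <- matrix(sample(1:max_depth, n_sites * n_pools, replace = TRUE),
               n_sites, n_pools)
  altc <- matrix(rbinom(n_sites * n_pools, as.vector(rd), 0.3),
                 n_sites, n_pools)
  # guarantee at least one alternate read somewhere per site (sync survives)
  altc[, 1] <- pmax(altc[, 1], 1L)
  tibble::tibble(
    chrom = rep(rep("chr1", n_sites), n_pools),
    pos = rep(seq(100, by = 97, length.out = n_sites), n_pools),
    ref = rep(ref, n_pools),
    alt = rep(alt, n_pools),
    pool_id = rep(pools, each = n_sites),
    ref_count = as.integer(rd - altc),
    alt_count = as.integer(altc)
  )
}

meta_for <- function(counts, n = 50) {
  ids <- unique(counts$pool_id)
  tibble::tibble(pool_id = ids,
                 n_individuals = rep_len(n, length(ids)))
}

# Build a frequency table directly from a site x pool matrix of frequencies
# (bypasses counts; for formula-level tests).
freq_from_matrix <- function(m, chrom = "chr1", pos = NULL) {
  pos <- pos %||% seq_len(nrow(m)) * 10L
  pools <- colnames(m) %||% sprintf("P%d", seq_len(ncol(m)))
  tibble::tibble(
    chrom = rep(chrom, length.out = nrow(m) * ncol(m)),
    pos = rep(pos, times = ncol(m)),
    pool_id = rep(pools, each = nrow(m)),
    rd = 1000L,
    f = as.vector(m),
    n_eff = 100
  )
}
`%||%` <- rlang::`%||%`

# Independent brute-force merge-then-filter oracle for independent-locus
# clustering: single linkage on gaps < merge_dist, then the span and
# strong-SNP filters, via explicit loops.
brute_force_loci <- function(chrom, pos, p_raw, min_span = 100,
                             strong_p = 1e-20, merge_dist = 1e5) {
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; p_raw <- p_raw[ord]
  out <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    groups <- list(); current <- i[1]
    for (k in i[-1]) {
      if (pos[k] - pos[current[length(current)]] < merge_dist) {
        current <- c(current, k)
      } else {
        groups[[length(groups) + 1]] <- current
        current <- k
      }
    }
    groups[[length(groups) + 1]] <- current
    for (g in groups) {
      span <- max(pos[g]) - min(pos[g]) + 1L
      n_strong <- sum(p_raw[g] < strong_p)
      if (span >= min_span && n_strong >= 2) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start = min(pos[g]), end = max(pos[g]),
          span = span, n_snps = length(g), n_strong = n_strong)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), span = integer(),
                          n_snps = integer(), n_strong = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# Brute-force per-site pool F_ST from the pi definitions, scalar loops.
brute_force_fst <- function(ref_a, alt_a, ref_b, alt_b) {
  rd_a <- ref_a + alt_a; rd_b <- ref_b + alt_b
  if (rd_a < 2 || rd_b < 2) return(NA_real_)
  f_a <- alt_a / rd_a; f_b <- alt_b / rd_b
  pi_a <- (rd_a / (rd_a - 1)) * 2 * f_a * (1 - f_a)
  pi_b <- (rd_b / (rd_b - 1)) * 2 * f_b * (1 - f_b)
  pi_s <- mean(c(pi_a, pi_b))
  rd_t <- rd_a + rd_b
  f_t <- (alt_a + alt_b) / rd_t
  pi_t <- (rd_t / (rd_t - 1)) * 2 * f_t * (1 - f_t)
  if (pi_t == 0) return(NA_real_)
  (pi_t - pi_s) / pi_t
}

# Brute-force Nei (1972) distance between two frequency vectors, loops.
brute_force_nei <- function(x, y) {
  jxy <- jx <- jy <- 0
  for (s in seq_along(x)) {
    if (is.na(x[s]) || is.na(y[s])) next
    jxy <- jxy + x[s] * y[s] + (1 - x[s]) * (1 - y[s])
    jx <- jx + x[s]^2 + (1 - x[s])^2
    jy <- jy + y[s]^2 + (1 - y[s])^2
  }
  -log(jxy / sqrt(jx * jy))
}

# Brute-force nucleotide diversity: O(k^2 L) pairwise comparison.
brute_force_pi <- function(haps, span_bp) {
  k <- nrow(haps)
  total <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      total <- total + sum(haps[i, ] != haps[j, ])
    }
  }
  total / choose(k, 2) / span_bp
}

# The structured default fixture is expensive enough to share across tests;
# built once per session on first use.
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    cfg <- sim_config(seed = 20260925)
    truth <- simulate_truth(cfg)
    counts <- simulate_pools(truth)
    .fixture_cache$fx <- list(cfg = cfg, truth = truth, counts = counts)
  }
  .fixture_cache$fx
}

superpool_ids <- function(truth, label) {
  truth$pools$pool_id[truth$pools$superpool == label]
}
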