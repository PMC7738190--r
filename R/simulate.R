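#' Configuration for the synthetic pool-seq generator
#'
#' Defines study conditions mirroring a large pool-seq population survey:
#' tens of pools of 35-110 diploids sequenced to a mean depth of at least
#' 30x, weak hierarchical baseline differentiation (Balding-Nichols
#' divergence `fst` on the scale of observed pairwise F_ST of a few
#' percent), a small number of planted selected loci with large
#' superpool allele-frequency shifts, and optionally a megabase
#' inversion-like block segregating as two haplotype classes.
#'
#' @param n_pools Number of population pools (default 20).
#' @param pool_size_range Range of diploid individuals per pool, sampled
#'   uniformly (default `c(35, 110)`).
#' @param superpool Superpool label per pool; default splits pools in half
#'   into `"A"` and `"B"`.
#' @param n_sites Total number of SNP sites (default 50000).
#' @param n_chrom Number of chromosomes the sites are spread over (default 5).
#' @param site_spacing Distance between adjacent sites in bp (default 1000).
#' @param n_selected_loci Number of planted selected loci (default 50; 0
#'   gives a null dataset).
#' @param sites_per_locus Consecutive sites per planted locus (default 5).
#' @param delta_range Allele-frequency shift of superpool A at selected
#'   sites, drawn per locus (default `c(0.5, 0.7)`).
#' @param fst Balding-Nichols divergence parameter F in (0, 1); `0` gives
#'   identical pool frequencies (default 0.03).
#' @param depth Mean read depth per pool (Poisson; default 50).
#' @param p0_range Range of the uniform ancestral allele frequency, bounded
#'   away from 0/1 so MAF filters stay exercised (default `c(0.05, 0.95)`).
#' @param inversion Optional [inversion_spec()]; `NULL` (default) for none.
#' @param seed Integer seed; all downstream draws derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pools = 20,
                       pool_size_range = c(35, 110),
                       superpool = NULL,
                       n_sites = 50000,
                       n_chrom = 5,
                       site_spacing = 1000,
                       n_selected_loci = 50,
                       sites_per_locus = 5,
                       delta_range = c(0.5, 0.7),
                       fst = 0.03,
                       depth = 50,
                       p0_range = c(0.05, 0.95),
                       inversion = NULL,
                       seed = 1) {
  superpool <- superpool %||% c(rep("A", ceiling(n_pools / 2)),
                                rep("B", floor(n_pools / 2)))
  stopifnot(length(superpool) == n_pools,
            fst >= 0, fst < 1, depth >= 1,
            delta_range[1] > 0, delta_range[2] <= 1,
            n_selected_loci >= 0, sites_per_locus >= 1)
  structure(
    list(n_pools = n_pools, pool_size_range = pool_size_range,
         superpool = superpool, n_sites = n_sites, n_chrom = n_chrom,
         site_spacing = site_spacing, n_selected_loci = n_selected_loci,
         sites_per_locus = sites_per_locus, delta_range = delta_range,
         fst = fst, depth = depth, p0_range = p0_range,
         inversion = inversion, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Inversion-like block specification
#'
#' A megabase region segregating as two deeply diverged haplotype classes
#' (N and S): inside the block every site is near-fixed for alternative
#' alleles between the classes (`p_s` vs `p_n`, allele orientation
#' randomized per site), and a pool's site frequencies are the mixture
#' `q * p_s + (1 - q) * p_n` given its S-haplotype frequency `q`.
#'
#' @param chrom Chromosome carrying the block (default `"chr5"`).
#' @param start,end Block span in bp, 1-based inclusive (default 2 Mb:
#'   4,000,001-6,000,000).
#' @param q Per-pool true S-haplotype frequencies; default an evenly spaced
#'   schedule over `[0, 1]`, so the extreme pools are fixed for one
#'   arrangement and can serve as reference groups (recycled to the number
#'   of pools at simulation time).
#' @param p_s,p_n Within-class frequencies of the S-associated allele
#'   (defaults 0.95 and 0.05).
#' @return An `inversion_spec` list.
#' @export
inversion_spec <- function(chrom = "chr5", start = 4000001, end = 6000000,
                           q = NULL, p_s = 0.95, p_n = 0.05) {
  stopifnot(end >= start, p_s > p_n)
  structure(list(chrom = chrom, start = start, end = end, q = q,
                 p_s = p_s, p_n = p_n),
            class = "inversion_spec")
}

#' Simulate true population allele frequencies
#'
#' Draws the latent truth of a pool-seq survey. Neutral sites: ancestral
#' frequency `p0 ~ Uniform(p0_range)` and, independently per pool,
#' Balding-Nichols frequencies
#' `p_k ~ Beta(p0 (1 - F)/F, (1 - p0)(1 - F)/F)` (so
#' `Var(p_k) = F p0 (1 - p0)`). Selected loci are contiguous runs of sites
#' where superpool-A pools have `p_k` shifted by `+delta` (clamped to
#' `[0.02, 0.98]`). Inside an inversion block, pool frequencies follow the
#' two-haplotype mixture of [inversion_spec()], overriding any planted
#' shift.
#'
#' @param cfg A [sim_config()].
#' @return A `pool_sim` object: list with `config`, `pools` (tibble
#'   `pool_id`, `n_individuals`, `superpool`), `sites` (tibble `chrom`,
#'   `pos`, `p0`, `selected`, `locus_id`, `in_inversion`, `s_allele`), `p`
#'   (sites x pools matrix of true frequencies), `inversion` (spec with
#'   resolved `q`, or `NULL`).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_pools <- cfg$n_pools
  pools <- tibble(
    pool_id = sprintf("P%02d", seq_len(n_pools)),
    n_individuals = {
      sizes <- seq.int(cfg$pool_size_range[1], cfg$pool_size_range[2])
      sizes[sample.int(length(sizes), n_pools, replace = TRUE)]
    },
    superpool = cfg$superpool
  )

  per_chrom <- ceiling(cfg$n_sites / cfg$n_chrom)
  chrom <- rep(sprintf("chr%d", seq_len(cfg$n_chrom)), each = per_chrom)[seq_len(cfg$n_sites)]
  pos <- rep(cfg$site_spacing * seq_len(per_chrom), times = cfg$n_chrom)[seq_len(cfg$n_sites)]
  n_sites <- cfg$n_sites

  p0 <- runif(n_sites, cfg$p0_range[1], cfg$p0_range[2])
  if (cfg$fst == 0) {
    p <- matrix(p0, n_sites, n_pools)
  } else {
    ratio <- (1 - cfg$fst) / cfg$fst
    p <- matrix(
      rbeta(n_sites * n_pools,
            shape1 = rep(p0, n_pools) * ratio,
            shape2 = rep(1 - p0, n_pools) * ratio),
      n_sites, n_pools)
  }
  colnames(p) <- pools$pool_id

  # plant selected loci: evenly spread anchors, runs of consecutive sites
  selected <- rep(FALSE, n_sites)
  locus_id <- rep(NA_integer_, n_sites)
  if (cfg$n_selected_loci > 0) {
    stride <- n_sites %/% cfg$n_selected_loci
    if (stride < cfg$sites_per_locus + 100) {
      abort("too many selected loci for the number of sites")
    }
    anchors <- (seq_len(cfg$n_selected_loci) - 1L) * stride + stride %/% 2L
    deltas <- runif(cfg$n_selected_loci, cfg$delta_range[1], cfg$delta_range[2])
    a_pools <- which(cfg$superpool == "A")
    for (l in seq_len(cfg$n_selected_loci)) {
      idx <- anchors[l] + seq_len(cfg$sites_per_locus) - 1L
      idx <- idx[idx <= n_sites]
      idx <- idx[chrom[idx] == chrom[anchors[l]]]
      selected[idx] <- TRUE
      locus_id[idx] <- l
      p[idx, a_pools] <- pmin(pmax(p[idx, a_pools] + deltas[l], 0.02), 0.98)
    }
  }

  # inversion block: two-haplotype mixture overrides the baseline
  in_inversion <- rep(FALSE, n_sites)
  s_allele <- rep(NA_character_, n_sites)
  inv <- cfg$inversion
  if (!is.null(inv)) {
    inv$q <- inv$q %||% seq(0, 1, length.out = n_pools)
    inv$q <- rep(inv$q, length.out = n_pools)
    names(inv$q) <- pools$pool_id
    inside <- chrom == inv$chrom & pos >= inv$start & pos <= inv$end
    if (!any(inside)) abort("inversion block contains no sites")
    in_inversion <- inside
    s_is_alt <- runif(sum(inside)) < 0.5
    s_allele[inside] <- ifelse(s_is_alt, "alt", "ref")
    p_site_s <- ifelse(s_is_alt, inv$p_s, 1 - inv$p_s)
    p_site_n <- ifelse(s_is_alt, inv$p_n, 1 - inv$p_n)
    p[inside, ] <- outer(p_site_s, inv$q) + outer(p_site_n, 1 - inv$q)
    selected[inside] <- FALSE
    locus_id[inside] <- NA_integer_
  }

  structure(
    list(
      config = cfg,
      pools = pools,
      sites = tibble(chrom = chrom, pos = as.integer(pos), p0 = p0,
                     selected = selected, locus_id = locus_id,
                     in_inversion = in_inversion, s_allele = s_allele),
      p = p,
      inversion = inv
    ),
    class = "pool_sim"
  )
}

#' @export
print.pool_sim <- function(x, ...) {
  cat(sprintf("<pool_sim> %d pools x %d sites, F = %g, %d selected loci%s\n",
              nrow(x$pools), nrow(x$sites), x$config$fst,
              x$config$n_selected_loci,
              if (is.null(x$inversion)) "" else ", 1 inversion block"))
  invisible(x)
}

#' Simulate pooled read counts from the truth
#'
#' Two-stage sampling, so that the N_eff allele-count correction has real
#' variance to correct: per pool and site, `2n` chromosomes are drawn from
#' the population frequency (`a ~ Binomial(2n, p)`), read depth is
#' `RD ~ Poisson(depth)` floored at 1, and alternate reads are
#' `Binomial(RD, a / 2n)`. Reference/alternate nucleotides are assigned at
#' random per site. Deterministic given `seed`.
#'
#' @param truth A `pool_sim` from [simulate_truth()].
#' @param seed Seed for the sampling stage; defaults to the config seed + 1.
#' @return A long counts tibble (`chrom`, `pos`, `ref`, `alt`, `pool_id`,
#'   `ref_count`, `alt_count`) compatible with the whole pipeline.
#' @export
simulate_pools <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "pool_sim"))
  set.seed(seed %||% (truth$config$seed + 1L))
  n_sites <- nrow(truth$sites)
  n_pools <- nrow(truth$pools)
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))

  two_n <- rep(2L * truth$pools$n_individuals, each = n_sites)
  a <- rbinom(n_sites * n_pools, size = two_n, prob = as.vector(truth$p))
  rd <- pmax(1L, rpois(n_sites * n_pools, truth$config$depth))
  alt_count <- rbinom(n_sites * n_pools, size = rd, prob = a / two_n)

  tibble(
    chrom = rep(truth$sites$chrom, times = n_pools),
    pos = rep(truth$sites$pos, times = n_pools),
    ref = rep(ref, times = n_pools),
    alt = rep(alt, times = n_pools),
    pool_id = rep(truth$pools$pool_id, each = n_sites),
    ref_count = as.integer(rd - alt_count),
    alt_count = as.integer(alt_count)
  )
}

#' Simulate phased haplotypes for the inversion block
#'
#' Builds two ancestral block haplotypes that differ at every in-block site
#' (the S haplotype carries the S-associated allele), then derives
#' `k_per_group` haplotypes per class by flipping each site independently
#' with probability `theta`. Group labels `"S"`/`"N"` are attached.
#'
#' @param truth A `pool_sim` whose config includes an inversion.
#' @param k_per_group Haplotypes per class (default 20).
#' @param theta Per-site mutation probability (default 0.01).
#' @param seed Seed; defaults to the config seed + 2.
#' @return A [hap_alignment()] over the in-block sites.
#' @export
simulate_haplotypes <- function(truth, k_per_group = 20, theta = 0.01,
                                seed = NULL) {
  if (is.null(truth$inversion)) abort("truth has no inversion block configured")
  set.seed(seed %||% (truth$config$seed + 2L))
  idx <- which(truth$sites$in_inversion)
  anc_s <- as.integer(truth$sites$s_allele[idx] == "alt")
  anc_n <- 1L - anc_s
  L <- length(idx)
  k <- 2L * k_per_group
  base <- rbind(
    matrix(anc_s, k_per_group, L, byrow = TRUE),
    matrix(anc_n, k_per_group, L, byrow = TRUE)
  )
  flips <- matrix(runif(k * L) < theta, k, L)
  haps <- abs(base - flips)
  storage.mode(haps) <- "integer"
  rownames(haps) <- c(sprintf("S%02d", seq_len(k_per_group)),
                      sprintf("N%02d", seq_len(k_per_group)))
  sites <- tibble(chrom = truth$sites$chrom[idx],
                  pos = truth$sites$pos[idx],
                  ref = "A", alt = "C")
  hap_alignment(haps, sites,
                group = rep(c("S", "N"), each = k_per_group))
}

#' True locus intervals of a simulation
#'
#' @param truth A `pool_sim`.
#' @return A tibble `locus_id`, `chrom`, `start`, `end`.
#' @export
true_loci <- function(truth) {
  truth$sites |>
    filter(!is.na(.data$locus_id)) |>
    group_by(.data$locus_id, .data$chrom) |>
    summarise(start = min(.data$pos), end = max(.data$pos), .groups = "drop") |>
    arrange(.data$locus_id)
}

#' Compare reported loci against planted truth
#'
#' A planted locus counts as recovered if any reported locus overlaps its
#' interval by at least 1 bp; a reported locus overlapping no planted locus
#' is a false discovery.
#'
#' @param loci Locus table from [cluster_loci()].
#' @param truth A `pool_sim`.
#' @return One-row tibble: `n_true`, `n_reported`, `n_recovered`,
#'   `n_false`, `sensitivity`, `fdr`.
#' @export
evaluate_loci <- function(loci, truth) {
  tl <- true_loci(truth)
  overlaps <- function(c1, s1, e1, c2, s2, e2) {
    c1 == c2 & s1 <= e2 & s2 <= e1
  }
  recovered <- vapply(seq_len(nrow(tl)), function(i) {
    any(overlaps(tl$chrom[i], tl$start[i], tl$end[i],
                 loci$chrom, loci$start, loci$end))
  }, logical(1))
  false_hit <- vapply(seq_len(nrow(loci)), function(i) {
    !any(overlaps(loci$chrom[i], loci$start[i], loci$end[i],
                  tl$chrom, tl$start, tl$end))
  }, logical(1))
  tibble(
    n_true = nrow(tl),
    n_reported = nrow(loci),
    n_recovered = sum(recovered),
    n_false = sum(false_hit),
    sensitivity = if (nrow(tl) > 0) sum(recovered) / nrow(tl) else NA_real_,
    fdr = if (nrow(loci) > 0) sum(false_hit) / nrow(loci) else 0
  )
}

#' Write a synthetic fixture to disk
#'
#' Emits the dataset in the pipeline's standard formats: a sync counts
#' file, tab-separated pool metadata, truth tables (per-site and per-pool),
#' and, when a haplotype alignment is supplied, a phased VCF. Everything
#' round-trips through the package readers.
#'
#' @param truth A `pool_sim`.
#' @param counts Counts from [simulate_pools()].
#' @param aln Optional [hap_alignment()] from [simulate_haplotypes()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory
#'   (default `FALSE`).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(truth, counts, aln = NULL, dir,
                          overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("directory %s exists and is not empty (set overwrite = TRUE)",
                  dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    sync = file.path(dir, "counts.sync"),
    metadata = file.path(dir, "pools.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_pools = file.path(dir, "truth_pools.tsv")
  )
  write_sync(counts, truth$pools, paths$sync)
  write_pool_metadata(truth$pools, paths$metadata)
  readr::write_tsv(truth$sites, paths$truth_sites, progress = FALSE)
  pool_truth <- truth$pools
  if (!is.null(truth$inversion)) {
    pool_truth$q_s <- truth$inversion$q[pool_truth$pool_id]
  }
  readr::write_tsv(pool_truth, paths$truth_pools, progress = FALSE)
  if (!is.null(aln)) {
    paths$vcf <- file.path(dir, "haplotypes.vcf")
    write_phased_vcf(aln, paths$vcf)
  }
  invisible(paths)
}
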