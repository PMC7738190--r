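small_cfg <- function(n_selected_loci = 4, ...) {
  sim_config(n_pools = 8, n_sites = 4000, n_chrom = 2,
             n_selected_loci = n_selected_loci, seed = 101, ...)
}

test_that("F = 0 collapses every pool onto the ancestral frequency", {
  truth <- simulate_truth(small_cfg(fst = 0, n_selected_loci = 0))
  expect_equal(max(abs(truth$p - truth$sites$p0)), 0)
})

test_that("Balding-Nichols variance matches F p0 (1 - p0) (Monte Carlo)", {
  cfg <- sim_config(n_pools = 40, n_sites = 10000, n_chrom = 1,
                    n_selected_loci = 0, fst = 0.05, seed = 102)
  truth <- simulate_truth(cfg)
  v_emp <- apply(truth$p, 1, var)
  v_exp <- cfg$fst * truth$sites$p0 * (1 - truth$sites$p0)
  expect_equal(mean(v_emp / v_exp), 1, tolerance = 0.1)
})

test_that("selected sites carry the configured superpool shift", {
  cfg <- small_cfg(delta_range = c(0.5, 0.5))
  truth <- simulate_truth(cfg)
  a <- truth$pools$superpool == "A"
  # away from the [0.02, 0.98] clamp the mean shift equals delta
  sel <- truth$sites$selected & truth$sites$p0 < 0.35
  shift <- rowMeans(truth$p[sel, a, drop = FALSE]) -
    rowMeans(truth$p[sel, !a, drop = FALSE])
  expect_equal(mean(shift), 0.5, tolerance = 0.05)
  expect_true(all(truth$p >= 0 & truth$p <= 1))
})

test_that("selected sites form contiguous loci with the configured run length", {
  truth <- simulate_truth(small_cfg())
  tl <- true_loci(truth)
  expect_equal(nrow(tl), 4)
  runs <- dplyr::count(dplyr::filter(truth$sites, !is.na(locus_id)), locus_id)
  expect_true(all(runs$n == truth$config$sites_per_locus))
  # loci far enough apart to stay independent after 100 kb merging
  gaps <- tl$start[-1] - tl$end[-nrow(tl)]
  same_chrom <- tl$chrom[-1] == tl$chrom[-nrow(tl)]
  expect_true(all(gaps[same_chrom] > 2e5))
})

test_that("read depth and frequencies are unbiased; same seed is identical", {
  cfg <- small_cfg(n_selected_loci = 0, depth = 50)
  truth <- simulate_truth(cfg)
  counts <- simulate_pools(truth)
  rd <- counts$ref_count + counts$alt_count
  expect_equal(mean(rd), 50, tolerance = 0.02)
  f_obs <- mean(counts$alt_count / rd)
  expect_equal(f_obs, mean(truth$p), tolerance = 0.01)

  counts2 <- simulate_pools(simulate_truth(cfg))
  expect_identical(counts, counts2)
  expect_false(identical(counts, simulate_pools(truth, seed = 777)))
})

test_that("inversion blocks mix two near-fixed haplotype classes", {
  cfg <- sim_config(n_pools = 6, n_sites = 3000, n_chrom = 3,
                    n_selected_loci = 0, seed = 103,
                    inversion = inversion_spec(chrom = "chr3",
                                               start = 200001, end = 700000))
  truth <- simulate_truth(cfg)
  inv <- truth$sites$in_inversion
  expect_equal(sum(inv), 500)
  expect_true(all(truth$sites$chrom[inv] == "chr3"))
  q <- truth$inversion$q
  # site frequency of the S allele equals q (mixture is exact in truth)
  p_s_allele <- truth$p[inv, , drop = FALSE]
  flip <- truth$sites$s_allele[inv] == "ref"
  p_s_allele[flip, ] <- 1 - p_s_allele[flip, ]
  want <- outer(rep(1, sum(inv)), q * 0.95 + (1 - q) * 0.05)
  expect_equal(unname(p_s_allele), unname(want), tolerance = 1e-12)
})

test_that("simulated haplotypes respect theta and split monophyletically", {
  cfg <- sim_config(n_pools = 6, n_sites = 2000, n_chrom = 2,
                    n_selected_loci = 0, seed = 104,
                    inversion = inversion_spec(chrom = "chr2",
                                               start = 1, end = 100000))
  truth <- simulate_truth(cfg)

  aln0 <- simulate_haplotypes(truth, k_per_group = 5, theta = 0)
  expect_equal(nucleotide_diversity(aln0, group = "S"), 0)
  expect_equal(nucleotide_diversity(aln0, group = "N"), 0)
  s <- aln0$haplotypes[aln0$group == "S", 1, drop = FALSE]
  n <- aln0$haplotypes[aln0$group == "N", 1, drop = FALSE]
  # the two ancestral classes differ at every site
  expect_true(all(aln0$haplotypes[1, ] != aln0$haplotypes[10, ]))

  aln <- simulate_haplotypes(truth, k_per_group = 10, theta = 0.05)
  span <- diff(range(aln$sites$pos)) + 1
  pi_s <- nucleotide_diversity(aln, group = "S", span_bp = span)
  expected <- 2 * 0.05 * (1 - 0.05) * ncol(aln$haplotypes) / span
  expect_equal(pi_s, expected, tolerance = 0.5)

  d <- stats::dist(aln$haplotypes, method = "manhattan")
  tree <- nj_pool_tree(as.matrix(d))
  rooted <- ape::root(tree, rownames(aln$haplotypes)[1])
  expect_true(ape::is.monophyletic(rooted,
                                   rownames(aln$haplotypes)[aln$group == "N"]))
})

test_that("fixtures round-trip through the package readers", {
  cfg <- sim_config(n_pools = 4, n_sites = 300, n_chrom = 1,
                    n_selected_loci = 0, seed = 105,
                    inversion = inversion_spec(chrom = "chr1", start = 1,
                                               end = 50000))
  truth <- simulate_truth(cfg)
  counts <- simulate_pools(truth)
  aln <- simulate_haplotypes(truth, k_per_group = 3, theta = 0.01)
  dir <- withr::local_tempdir()
  paths <- write_fixture(truth, counts, aln, file.path(dir, "fx"))

  meta <- read_pool_metadata(paths$metadata)
  expect_equal(meta$pool_id, truth$pools$pool_id)
  back <- read_sync(paths$sync, meta)
  key <- function(x) dplyr::arrange(tibble::as_tibble(x), chrom, pos, pool_id)
  expect_equal(key(back), key(counts), ignore_attr = TRUE)

  ts <- readr::read_tsv(paths$truth_sites, show_col_types = FALSE)
  expect_equal(nrow(ts), cfg$n_sites)

  vcf <- read_phased_vcf(paths$vcf)
  expect_equal(unname(vcf$haplotypes), unname(aln$haplotypes))

  expect_error(write_fixture(truth, counts, aln, file.path(dir, "fx")),
               "overwrite")
})
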