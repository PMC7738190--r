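test_that("Nei distance reproduces hand-computed identities", {
  m <- cbind(X = c(1, 0.5), Y = c(0.5, 0.5))
  fr <- freq_from_matrix(m)
  # identical vectors -> D = 0
  d_same <- nei_distance(freq_from_matrix(cbind(A = c(0.3, 0.7),
                                                B = c(0.3, 0.7))))
  expect_equal(unname(d_same["A", "B"]), 0)
  # single site, x = 1, y = 0.5: I = 0.5 / sqrt(0.5) -> D = -ln(0.7071)
  d <- nei_distance(freq_from_matrix(cbind(X = 1, Y = 0.5), pos = 10L))
  expect_equal(unname(d["X", "Y"]), -log(0.5 / sqrt(0.5)), tolerance = 1e-10)
  # opposite fixation: I = 0 -> capped
  expect_warning(
    d0 <- nei_distance(freq_from_matrix(cbind(X = 1, Y = 0), pos = 10L),
                       max_distance = 50),
    "capped")
  expect_equal(unname(d0["X", "Y"]), 50)
})

test_that("Nei distance matches the brute-force loop, NA cells excluded", {
  set.seed(17)
  m <- matrix(runif(60), 15, 4, dimnames = list(NULL, paste0("P", 1:4)))
  m[sample(60, 6)] <- NA
  d <- nei_distance(freq_from_matrix(m))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(unname(d[i, j]), brute_force_nei(m[, i], m[, j]),
                 tolerance = 1e-10)
  }
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("neighbor joining inverts additive distances exactly", {
  # ((A:1,B:2):1,(C:3,D:4)); additive leaf-to-leaf matrix by hand
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- nj_pool_tree(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(d), rownames(d)],
               d, tolerance = 1e-10)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("neighbor joining recovers random trees up to 12 leaves", {
  set.seed(18)
  for (n in c(4, 6, 8, 12)) {
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- as.matrix(ape::cophenetic.phylo(true_tree))
    got <- nj_pool_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(true_tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(as.matrix(ape::cophenetic.phylo(got))[rownames(d), rownames(d)],
                 d, tolerance = 1e-8)
  }
})

test_that("three taxa give the three-point branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_pool_tree(d)
  len <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(unname(len["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["C"]), (4 + 5 - 3) / 2)
})

test_that("negative branch lengths are floored, never emitted", {
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0) * 1.0, 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "c"] <- d["c", "a"] <- 0.5  # deliberately non-additive
  tree <- nj_pool_tree(d)
  expect_true(all(tree$edge.length >= 0))
  expect_error(nj_pool_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("bootstrap consensus is deterministic and unanimous when clean", {
  set.seed(19)
  # two well-separated groups of pools; every replicate finds the split
  m <- cbind(
    matrix(runif(40, 0.0, 0.1), 20, 2),
    matrix(runif(40, 0.9, 1.0), 20, 2),
    matrix(runif(20, 0.45, 0.55), 20, 1)
  )
  colnames(m) <- c("L1", "L2", "R1", "R2", "M")
  fr <- freq_from_matrix(m)
  t1 <- bootstrap_consensus(fr, n_reps = 50, seed = 123)
  t2 <- bootstrap_consensus(fr, n_reps = 50, seed = 123)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(as.numeric(t1$node.label) == 100 |
                    is.na(as.numeric(t1$node.label))))
  # the L vs R split must be present
  split_found <- ape::is.monophyletic(ape::root(t1, "M"), c("L1", "L2")) ||
    ape::is.monophyletic(ape::root(t1, "M"), c("R1", "R2"))
  expect_true(split_found)
})

test_that("nucleotide diversity matches brute force and the boundary cases", {
  # haplotypes AAA, AAT, ATT encoded as alt indicators over span 3
  haps <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1))
  aln <- hap_alignment(haps, tibble::tibble(chrom = "c", pos = 1:3))
  expect_equal(nucleotide_diversity(aln, span_bp = 3), 4 / 9)
  expect_equal(nucleotide_diversity(aln, span_bp = 3),
               brute_force_pi(haps, 3))

  same <- hap_alignment(rbind(c(1, 0), c(1, 0)),
                        tibble::tibble(chrom = "c", pos = 1:2))
  expect_equal(nucleotide_diversity(same, span_bp = 10), 0)

  alldiff <- hap_alignment(rbind(c(0, 0, 0), c(1, 1, 1)),
                           tibble::tibble(chrom = "c", pos = 1:3))
  expect_equal(nucleotide_diversity(alldiff, span_bp = 3), 1)

  set.seed(20)
  h <- matrix(rbinom(200, 1, 0.3), 10, 20)
  a <- hap_alignment(h, tibble::tibble(chrom = "c", pos = 1:20))
  expect_equal(nucleotide_diversity(a, span_bp = 500),
               brute_force_pi(h, 500))
})

test_that("group restriction and span validation work", {
  h <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 1))
  aln <- hap_alignment(h, tibble::tibble(chrom = "c", pos = 1:2),
                       group = c("S", "S", "N", "N"))
  expect_equal(nucleotide_diversity(aln, group = "N", span_bp = 2), 0)
  expect_equal(nucleotide_diversity(aln, group = "S", span_bp = 2),
               brute_force_pi(h[1:2, , drop = FALSE], 2))
  expect_error(nucleotide_diversity(aln, span_bp = 1), "span_bp")
  one <- hap_alignment(h[1, , drop = FALSE],
                       tibble::tibble(chrom = "c", pos = 1:2))
  expect_error(nucleotide_diversity(one, span_bp = 2), ">= 2 haplotypes")
})

test_that("haplotype frequencies average oriented diagnostic markers", {
  # 3 diagnostic sites (S fixed for alt, N for ref) + 1 uninformative
  m <- rbind(
    c(S1 = 0.95, S2 = 1.00, N1 = 0.05, N2 = 0.00, Q = 0.9),
    c(S1 = 1.00, S2 = 0.95, N1 = 0.00, N2 = 0.10, Q = 1.0),
    c(S1 = 0.05, S2 = 0.00, N1 = 0.95, N2 = 1.00, Q = 0.2),  # ref-oriented S
    c(S1 = 0.50, S2 = 0.55, N1 = 0.45, N2 = 0.50, Q = 0.5)
  )
  colnames(m) <- c("S1", "S2", "N1", "N2", "Q")
  fr <- freq_from_matrix(m)
  hf <- haplotype_frequency(fr, pools_s = c("S1", "S2"),
                            pools_n = c("N1", "N2"))
  diag <- attr(hf, "diagnostics")
  expect_equal(nrow(diag), 3)
  expect_equal(diag$s_allele, c("alt", "alt", "ref"))
  # pool Q: oriented frequencies are 0.9, 1.0, 1 - 0.2 = 0.8 -> mean 0.9
  expect_equal(hf$s_frequency[hf$pool_id == "Q"], 0.9)
  # reference S pools sit near fixation by construction
  expect_true(all(hf$s_frequency[hf$pool_id %in% c("S1", "S2")] >= 0.8))
  expect_error(haplotype_frequency(fr, c("S1", "S2"), c("N1", "N2"),
                                   diag_delta = 0.999), "diag_delta")
})
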