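meta2 <- tibble::tibble(pool_id = c("P1", "P2"), n_individuals = c(50L, 60L))

test_that("read_sync parses biallelic sites and applies the drop rules", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\t100\tA\t8:0:2:0:0:0\t5:0:5:0:0:0",   # ref A, alt C
    "chr1\t200\tA\t8:0:2:1:0:0\t5:0:0:0:0:0",   # A/C/G segregate -> drop
    "chr1\t300\tG\t0:3:0:7:1:2\t0:1:0:9:0:0"    # ref G, alt T; N/del ignored
  ), f)
  counts <- read_sync(f, meta2)
  expect_equal(attr(counts, "n_dropped"), 1)
  s1 <- dplyr::filter(counts, pos == 100)
  expect_equal(unique(s1$ref), "A")
  expect_equal(unique(s1$alt), "C")
  expect_equal(s1$ref_count[s1$pool_id == "P1"], 8L)
  expect_equal(s1$alt_count[s1$pool_id == "P1"], 2L)
  expect_equal(s1$ref_count[s1$pool_id == "P2"], 5L)
  expect_equal(s1$alt_count[s1$pool_id == "P2"], 5L)
  expect_false(200 %in% counts$pos)
  s3 <- dplyr::filter(counts, pos == 300)
  expect_equal(unique(s3$alt), "T")
  # RD excludes the N and del classes
  expect_equal(s3$ref_count[s3$pool_id == "P1"] + s3$alt_count[s3$pool_id == "P1"], 10L)
})

test_that("read_sync rejects malformed files", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\tA\t1:0:2:0:0:0\t2:0:1:0:0:0\t3:0:1:0:0:0", f)
  expect_error(read_sync(f, meta2), "3 count column")
  writeLines("chr1\t100\tA\t1:x:2:0:0:0\t2:0:1:0:0:0", f)
  expect_error(read_sync(f, meta2), "non-numeric")
})

test_that("alt allele ties break in A < C < G < T order", {
  f <- withr::local_tempfile()
  writeLines("chr1\t50\tT\t4:0:4:0:0:0\t0:0:0:0:0:0", f)  # A and C tied at 4
  counts <- read_sync(f, meta2)
  expect_equal(unique(counts$alt), "A")
})

test_that("sync writer round-trips randomized tables, zeros included", {
  counts <- random_counts(n_sites = 100, n_pools = 4, seed = 42)
  counts$alt_count[3] <- 0L  # a zero must serialize as "0", not blank
  meta <- meta_for(counts)
  f <- withr::local_tempfile()
  write_sync(counts, meta, f)
  back <- read_sync(f, meta)
  key <- function(x) dplyr::arrange(tibble::as_tibble(x), chrom, pos, pool_id)
  expect_equal(key(back), key(counts), ignore_attr = TRUE)
})

test_that("empty tables write an empty file and round-trip to empty", {
  empty <- random_counts(5)[0, ]
  f <- withr::local_tempfile()
  write_sync(empty, meta_for(random_counts(5)), f)
  expect_equal(file.size(f), 0)
  back <- read_sync(f, meta2)
  expect_equal(nrow(back), 0)
})

test_that("pool metadata reads, preserves labels, and validates", {
  f <- withr::local_tempfile()
  writeLines(c("pool_id\tn_individuals\tseason",
               "BAS1\t35\tspring", "ATL1\t110\tautumn"), f)
  meta <- read_pool_metadata(f)
  expect_equal(meta$pool_id, c("BAS1", "ATL1"))
  expect_identical(meta$n_individuals, c(35L, 110L))
  expect_equal(meta$season, c("spring", "autumn"))

  writeLines(c("pool_id\tn_individuals", "BAS1\t35", "BAS1\t40"), f)
  expect_error(read_pool_metadata(f), "duplicated pool_id")
  writeLines(c("pool_id\tn_individuals", "BAS1\t0"), f)
  expect_error(read_pool_metadata(f), "positive integers")
  writeLines(c("pool_id\tn_individuals", "BAS1\t35.5"), f)
  expect_error(read_pool_metadata(f), "positive integers")
})

test_that("phased VCF round-trips haplotypes and honours regions", {
  sites <- tibble::tibble(chrom = "chr2", pos = c(100L, 250L, 900L),
                          ref = c("A", "G", "T"), alt = c("C", "A", "G"))
  haps <- matrix(c(0L, 1L, 0L,
                   1L, 0L, 1L,
                   0L, 0L, 1L,
                   1L, 1L, 0L), nrow = 4, byrow = TRUE,
                 dimnames = list(c("s1_1", "s1_2", "s2_1", "s2_2"), NULL))
  aln <- hap_alignment(haps, sites)
  f <- withr::local_tempfile(fileext = ".vcf")
  poolscan:::write_phased_vcf(aln, f)

  back <- read_phased_vcf(f)
  expect_equal(unname(back$haplotypes), unname(haps))
  expect_equal(back$sites$pos, sites$pos)
  expect_equal(rownames(back$haplotypes), rownames(haps))

  sub <- read_phased_vcf(f, region = "chr2:200-1000")
  expect_equal(sub$sites$pos, c(250L, 900L))
  expect_equal(ncol(sub$haplotypes), 2)

  none <- read_phased_vcf(f, region = "chr2:1-50")
  expect_equal(ncol(none$haplotypes), 0)
  expect_equal(nrow(none$haplotypes), 4)  # 2N haplotypes survive
})

test_that("unphased genotypes error with the site named; multiallelics skip", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t10\t.\tA\tC\t.\tPASS\t.\tGT\t0/1"
  ), f)
  expect_error(read_phased_vcf(f), "unphased genotype at chr1:10")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t10\t.\tA\tC,T\t.\tPASS\t.\tGT\t1|2",
    "chr1\t20\t.\tA\tC\t.\tPASS\t.\tGT\t0|1"
  ), f)
  expect_message(aln <- read_phased_vcf(f), "multiallelic")
  expect_equal(aln$sites$pos, 20L)
})
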