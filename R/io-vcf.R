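#' Haplotype alignment
#'
#' Container for phased haplotypes over a set of biallelic SNP sites: an
#' integer matrix (haplotypes x sites, 0 = reference allele, 1 = alternate),
#' a site table, and an optional group label per haplotype (e.g. the N or S
#' arrangement of an inversion).
#'
#' @param haplotypes Integer 0/1 matrix, haplotypes in rows (rownames are
#'   haplotype ids), sites in columns.
#' @param sites Tibble with columns `chrom`, `pos` (and optionally `ref`,
#'   `alt`), one row per matrix column, sorted by position.
#' @param group Optional character vector of group labels, one per haplotype.
#' @return An object of class `hap_alignment`.
#' @export
hap_alignment <- function(haplotypes, sites, group = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (ncol(haplotypes) != nrow(sites)) {
    abort("number of alignment columns must equal number of sites")
  }
  if (nrow(sites) > 1 && is.unsorted(sites$pos)) {
    abort("sites must be sorted by position")
  }
  if (!is.null(group) && length(group) != nrow(haplotypes)) {
    abort("group must have one label per haplotype")
  }
  if (is.null(rownames(haplotypes))) {
    rownames(haplotypes) <- paste0("hap", seq_len(nrow(haplotypes)))
  }
  structure(
    list(haplotypes = haplotypes, sites = as_tibble(sites), group = group),
    class = "hap_alignment"
  )
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d haplotypes x %d sites\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read phased haplotypes from a VCF
#'
#' Extracts the two haplotypes of every diploid sample from phased genotypes
#' (`GT` values like `0|1`) at biallelic SNPs, optionally restricted to a
#' region. An unphased genotype (`0/1`) inside the region is an error naming
#' the offending site; multiallelic sites are skipped with a message.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param region Optional region string `"chrom:start-end"` (1-based,
#'   inclusive ends) or just `"chrom"`.
#' @return A [hap_alignment()] with two haplotypes per sample, named
#'   `<sample>_1` and `<sample>_2`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_samples <- ncol(vcf@gt) - 1L
  if (n_samples < 1) abort("VCF has no sample columns")
  samples <- colnames(vcf@gt)[-1]

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", region))[[1]]
    if (length(m) == 0) abort("region must look like 'chrom' or 'chrom:start-end'")
    keep <- fix$CHROM == m[2]
    if (m[3] != "") {
      pos <- as.integer(fix$POS)
      keep <- keep & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
    }
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi & keep)) {
    inform(sprintf("read_phased_vcf: skipped %d multiallelic site(s)",
                   sum(multi & keep)))
  }
  keep <- keep & !multi

  sites <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  hap_names <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  if (nrow(sites) == 0) {
    m <- matrix(integer(0), nrow = 2L * n_samples, ncol = 0,
                dimnames = list(hap_names, NULL))
    return(hap_alignment(m, sites))
  }

  gt <- vcf@gt[keep, -1, drop = FALSE]
  dims <- dim(gt)
  gt <- matrix(sub(":.*$", "", gt), dims[1], dims[2])  # strip fields after GT
  unphased <- matrix(grepl("/", gt, fixed = TRUE), dims[1], dims[2])
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, ]
    abort(sprintf("unphased genotype at %s:%d (sample %s)",
                  sites$chrom[bad[1]], sites$pos[bad[1]], samples[bad[2]]))
  }
  a1 <- suppressWarnings(matrix(as.integer(sub("\\|.*$", "", gt)), dims[1]))
  a2 <- suppressWarnings(matrix(as.integer(sub("^.*\\|", "", gt)), dims[1]))
  if (anyNA(a1) || anyNA(a2)) abort("malformed GT field in VCF")

  haps <- matrix(0L, nrow = 2L * n_samples, ncol = nrow(sites),
                 dimnames = list(hap_names, NULL))
  haps[seq(1, 2 * n_samples, by = 2), ] <- t(a1)
  haps[seq(2, 2 * n_samples, by = 2), ] <- t(a2)
  hap_alignment(haps, sites)
}

# Write a minimal phased VCF (plain text) from a haplotype alignment.
# Consecutive haplotype pairs form one diploid sample.
write_phased_vcf <- function(aln, path) {
  haps <- aln$haplotypes
  if (nrow(haps) %% 2 != 0) abort("need an even number of haplotypes")
  n_samples <- nrow(haps) / 2
  sample_names <- sub("_1$", "", rownames(haps)[seq(1, nrow(haps), by = 2)])
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  sites <- aln$sites
  ref <- sites$ref %||% rep("A", nrow(sites))
  alt <- sites$alt %||% rep("C", nrow(sites))
  gt_lines <- vapply(seq_len(nrow(sites)), function(s) {
    a1 <- haps[seq(1, nrow(haps), by = 2), s]
    a2 <- haps[seq(2, nrow(haps), by = 2), s]
    paste(paste0(a1, "|", a2), collapse = "\t")
  }, character(1))
  body <- paste(sites$chrom, sites$pos, ".", ref, alt, ".", "PASS", ".", "GT",
                gt_lines, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
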