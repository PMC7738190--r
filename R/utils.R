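# Internal helpers shared across modules.

# Canonical site key used to align tables; chrom then position.
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Validate a long counts table (one row per site x pool).
check_counts <- function(counts) {
  needed <- c("chrom", "pos", "ref", "alt", "pool_id", "ref_count", "alt_count")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(counts$pos < 1)) abort("positions must be >= 1 (1-based coordinates)")
  if (any(counts$ref_count < 0) || any(counts$alt_count < 0)) {
    abort("read counts must be non-negative")
  }
  invisible(counts)
}

check_metadata <- function(metadata) {
  needed <- c("pool_id", "n_individuals")
  missing <- setdiff(needed, names(metadata))
  if (length(missing) > 0) {
    abort(paste0("pool metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(metadata$pool_id)) {
    dup <- unique(metadata$pool_id[duplicated(metadata$pool_id)])
    abort(paste0("duplicated pool_id: ", paste(dup, collapse = ", ")))
  }
  n <- metadata$n_individuals
  if (any(is.na(n)) || any(n < 1) || any(n != round(n))) {
    abort("n_individuals must be positive integers")
  }
  invisible(metadata)
}

# Pivot a long counts table to aligned site x pool matrices.
# Sites ordered by (chrom, pos); pools in first-appearance order unless given.
count_matrices <- function(counts, pools = NULL) {
  check_counts(counts)
  sites <- distinct(counts, .data$chrom, .data$pos, .data$ref, .data$alt)
  sites <- arrange(sites, .data$chrom, .data$pos)
  if (anyDuplicated(site_key(sites$chrom, sites$pos))) {
    abort("counts table has more than one record per (chrom, pos)")
  }
  pools <- pools %||% unique(counts$pool_id)
  unknown <- setdiff(counts$pool_id, pools)
  if (length(unknown) > 0) {
    counts <- filter(counts, .data$pool_id %in% pools)
  }
  i <- match(site_key(counts$chrom, counts$pos), site_key(sites$chrom, sites$pos))
  j <- match(counts$pool_id, pools)
  dims <- c(nrow(sites), length(pools))
  ref_mat <- matrix(0L, dims[1], dims[2], dimnames = list(NULL, pools))
  alt_mat <- ref_mat
  ref_mat[cbind(i, j)] <- counts$ref_count
  alt_mat[cbind(i, j)] <- counts$alt_count
  list(sites = sites, pools = pools, ref = ref_mat, alt = alt_mat)
}

# Pivot a long frequency table (chrom, pos, pool_id, f, ...) to a site x pool
# matrix of a chosen value column; missing cells are NA.
freq_matrix <- function(freq, value = "f", pools = NULL) {
  sites <- distinct(freq, .data$chrom, .data$pos)
  sites <- arrange(sites, .data$chrom, .data$pos)
  pools <- pools %||% unique(freq$pool_id)
  keep <- freq$pool_id %in% pools
  i <- match(site_key(freq$chrom[keep], freq$pos[keep]),
             site_key(sites$chrom, sites$pos))
  j <- match(freq$pool_id[keep], pools)
  m <- matrix(NA_real_, nrow(sites), length(pools), dimnames = list(NULL, pools))
  m[cbind(i, j)] <- freq[[value]][keep]
  list(sites = sites, pools = pools, m = m)
}

# Row-wise sample sd of a matrix with NA cells (denominator n - 1).
row_sd <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- sqrt(ss / (n - 1))
  out[n < 2] <- NA_real_
  out
}
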