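#' Read a PoPoolation2-style sync file of pooled allele counts
#'
#' A sync file carries one row per genomic site: chromosome, 1-based position,
#' reference nucleotide, then one `A:T:C:G:N:del` count column per pool, in
#' the same order as `metadata`. The file is reduced to biallelic sites: the
#' alternate allele is the non-reference nucleotide with the highest count
#' summed across pools (ties broken in A < C < G < T order). Sites where more
#' than two nucleotides segregate, or where no alternate reads are observed in
#' any pool, are dropped; the number dropped is reported as a message and kept
#' in the `n_dropped` attribute. `N` and deletion counts never contribute to
#' read depth.
#'
#' @param path Path to a tab-separated sync file (no header).
#' @param metadata Pool metadata tibble with columns `pool_id` and
#'   `n_individuals`, one row per pool column in the file, in file order.
#' @return A tibble with one row per site and pool: `chrom`, `pos`, `ref`,
#'   `alt`, `pool_id`, `ref_count`, `alt_count`.
#' @seealso [write_sync()], [read_pool_metadata()]
#' @export
read_sync <- function(path, metadata) {
  check_metadata(metadata)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), pool_id = character(),
                  ref_count = integer(), alt_count = integer()))
  }
  n_pools <- nrow(metadata)
  if (ncol(raw) != 3 + n_pools) {
    abort(sprintf(
      "sync file has %d count column(s) but metadata describes %d pool(s)",
      ncol(raw) - 3, n_pools))
  }
  chrom <- raw[[1]]
  pos <- suppressWarnings(as.integer(raw[[2]]))
  if (anyNA(pos)) abort("non-numeric position in sync file")
  ref <- toupper(raw[[3]])
  if (!all(ref %in% c("A", "C", "G", "T"))) {
    abort("reference allele must be one of A, C, G, T")
  }

  nts <- c("A", "T", "C", "G")  # sync column order is A:T:C:G:N:del
  n_sites <- nrow(raw)
  # counts[site, nucleotide, pool]
  counts <- array(0L, dim = c(n_sites, 4L, n_pools))
  for (p in seq_len(n_pools)) {
    parts <- strsplit(raw[[3 + p]], ":", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 6)) {
      abort("each sync count field must have six colon-separated values (A:T:C:G:N:del)")
    }
    vals <- suppressWarnings(as.integer(unlist(parts, use.names = FALSE)))
    if (anyNA(vals)) abort("non-numeric count in sync file")
    m <- matrix(vals, ncol = 6, byrow = TRUE)
    counts[, , p] <- m[, 1:4]
  }

  total <- apply(counts, c(1, 2), sum)          # site x nucleotide totals
  colnames(total) <- nts
  ref_idx <- match(ref, nts)
  nonref <- total
  nonref[cbind(seq_len(n_sites), ref_idx)] <- -1L
  # alt = highest-count non-reference nucleotide; ties resolved A < C < G < T
  ord <- match(c("A", "C", "G", "T"), nts)
  alt_idx <- ord[max.col(nonref[, ord, drop = FALSE], ties.method = "first")]
  alt <- nts[alt_idx]

  n_segregating <- rowSums(total > 0)
  segregates_nonref <- total
  segregates_nonref[cbind(seq_len(n_sites), ref_idx)] <- 0L
  too_many <- n_segregating > 2
  no_alt <- rowSums(segregates_nonref) == 0
  drop <- too_many | no_alt
  if (any(drop)) {
    inform(sprintf("read_sync: dropped %d non-biallelic or alternate-free site(s)",
                   sum(drop)))
  }
  keep <- which(!drop)

  out <- tibble(
    chrom = rep(chrom[keep], times = n_pools),
    pos = rep(pos[keep], times = n_pools),
    ref = rep(ref[keep], times = n_pools),
    alt = rep(alt[keep], times = n_pools),
    pool_id = rep(metadata$pool_id, each = length(keep)),
    ref_count = as.integer(counts[cbind(
      rep(keep, times = n_pools),
      rep(ref_idx[keep], times = n_pools),
      rep(seq_len(n_pools), each = length(keep))
    )]),
    alt_count = as.integer(counts[cbind(
      rep(keep, times = n_pools),
      rep(alt_idx[keep], times = n_pools),
      rep(seq_len(n_pools), each = length(keep))
    )])
  )
  out <- arrange(out, .data$chrom, .data$pos)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Write pooled allele counts to a sync file
#'
#' Inverse of [read_sync()]: reference and alternate read counts are placed in
#' their nucleotide slots of the `A:T:C:G:N:del` field (other slots zero), one
#' column per pool in metadata order. `read_sync(write_sync(x))` reproduces
#' `x` for any table whose sites carry at least one alternate read.
#'
#' @param counts Long counts tibble as returned by [read_sync()].
#' @param metadata Pool metadata tibble (defines column order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(counts, metadata, path) {
  check_metadata(metadata)
  if (nrow(counts) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cm <- count_matrices(counts, pools = metadata$pool_id)
  nts <- c("A", "T", "C", "G")
  ref_idx <- match(cm$sites$ref, nts)
  alt_idx <- match(cm$sites$alt, nts)
  n_sites <- nrow(cm$sites)
  cols <- character(n_sites)
  fields <- matrix("", n_sites, length(cm$pools))
  for (p in seq_along(cm$pools)) {
    slot <- matrix(0L, n_sites, 6)
    slot[cbind(seq_len(n_sites), ref_idx)] <- cm$ref[, p]
    slot[cbind(seq_len(n_sites), alt_idx)] <- cm$alt[, p]
    fields[, p] <- paste(slot[, 1], slot[, 2], slot[, 3], slot[, 4],
                         slot[, 5], slot[, 6], sep = ":")
  }
  lines <- paste(cm$sites$chrom, cm$sites$pos, cm$sites$ref,
                 apply(fields, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
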