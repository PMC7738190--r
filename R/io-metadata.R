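#' Read pool metadata
#'
#' Tab-separated with a header line; columns `pool_id` and `n_individuals`
#' (number of diploid individuals in the pool) are required, any further
#' columns (region, spawning season, superpool tags, ...) are kept verbatim
#' as labels. Pool order in the file is preserved.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A tibble, one row per pool.
#' @export
read_pool_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    pool_id = readr::col_character(),
    n_individuals = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  check_metadata(meta)
  meta$n_individuals <- as.integer(meta$n_individuals)
  meta
}

#' Write pool metadata
#'
#' @param metadata A pool metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_metadata <- function(metadata, path) {
  check_metadata(metadata)
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}
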