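#' Write predicted sites as BED6
#'
#' Sites are written as 0-based half-open intervals; the BED score column
#' carries the mismatch count.
#'
#' @param sites Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`, and optionally `nuclease_id` (used
#'   as the BED name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  req <- c("chrom", "start", "end", "strand", "mismatches")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(sites) > 0L && any(sites$end <= sites$start)) {
    stop("BED intervals must satisfy end > start")
  }
  name <- if ("nuclease_id" %in% names(sites)) sites$nuclease_id else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   sites$chrom, as.integer(sites$start),
                   as.integer(sites$end), name,
                   as.integer(sites$mismatches), sites$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of predicted sites
#'
#' @param path Path to a BED6 file written by [write_bed()].
#' @return Tibble with `chrom`, `start`, `end`, `nuclease_id`, `mismatches`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "nuclease_id", "mismatches", "strand")
  tbl <- readr::read_tsv(
    path, col_names = cols,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), nuclease_id = readr::col_character(),
      mismatches = readr::col_integer(), strand = readr::col_character()
    ),
    progress = FALSE
  )
  tibble::as_tibble(tbl)
}
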