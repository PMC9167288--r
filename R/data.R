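#' Published whole-genome audit tables for the moss APT editing study
#'
#' Small reference tables from a whole-genome specificity audit of
#' CRISPR-Cas9- and TALEN-edited *Physcomitrium patens* plants, shipped with
#' the package as worked-example inputs:
#'
#' * `apt_editing_counts()` — per-plant SNV and InDel counts relative to the
#'   matched wild type, for control, PEG-treated, PEG+DNA, CRISPR-edited and
#'   TALEN-edited plants (one PEG+DNA plant is `excluded`: its library was
#'   contaminated and carries NA counts);
#' * `apt_editing_efficiency()` — regenerant and resistant-clone counts per
#'   editing strategy, input to [mutation_efficiency()];
#' * `apt_editing_totals()` — genome-wide totals of detected SNVs and InDels
#'   across all samples.
#'
#' @return A tibble (see above for columns).
#' @export
apt_editing_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "apt_editing_plant_counts.tsv",
                package = "editaudit", mustWork = TRUE),
    col_types = readr::cols(
      sample_id = readr::col_character(),
      experiment = readr::col_character(),
      n_snv = readr::col_integer(),
      n_indel = readr::col_integer(),
      excluded = readr::col_logical()
    ),
    progress = FALSE
  )
}

#' @rdname apt_editing_counts
#' @export
apt_editing_efficiency <- function() {
  readr::read_tsv(
    system.file("extdata", "apt_editing_efficiency.tsv",
                package = "editaudit", mustWork = TRUE),
    col_types = readr::cols(
      strategy = readr::col_character(),
      regenerants = readr::col_integer(),
      resistant = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' @rdname apt_editing_counts
#' @export
apt_editing_totals <- function() {
  readr::read_tsv(
    system.file("extdata", "apt_editing_detection_totals.tsv",
                package = "editaudit", mustWork = TRUE),
    col_types = readr::cols(
      var_type = readr::col_character(),
      n_detected = readr::col_integer()
    ),
    progress = FALSE
  )
}
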