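#' Sample metadata: read, validate, write
#'
#' The sample-metadata table describes the experimental design: which
#' experiment group (protoplast batch / wild-type pedigree) each plant
#' belongs to, which wild type anchors its lineage, and its treatment role.
#'
#' Columns:
#' * `sample_id` — unique sample name.
#' * `experiment_group` — pedigree/batch label (e.g. `"A"`, `"B"`, `"C"`).
#' * `lineage_wt` — `sample_id` of the matched wild type (self for wild
#'   types).
#' * `role` — one of `wildtype`, `control`, `peg`, `peg_dna`, `edited`.
#' * `nuclease_id` — nuclease used, for `edited` samples (NA otherwise).
#' * `excluded` — logical; excluded samples (e.g. contaminated libraries)
#'   take no part in filtering or classification.
#'
#' @param path Path to a tab-separated metadata table.
#' @return A validated metadata tibble.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      experiment_group = readr::col_character(),
      lineage_wt = readr::col_character(),
      role = readr::col_character(),
      nuclease_id = readr::col_character(),
      excluded = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_metadata(tibble::as_tibble(tbl))
}

#' @rdname read_metadata
#' @param metadata A metadata tibble.
#' @export
validate_metadata <- function(metadata) {
  req <- c("sample_id", "experiment_group", "lineage_wt", "role")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0L) {
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"nuclease_id" %in% names(metadata)) {
    metadata$nuclease_id <- NA_character_
  }
  if (!"excluded" %in% names(metadata)) metadata$excluded <- FALSE
  metadata$excluded[is.na(metadata$excluded)] <- FALSE
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata")
  }
  roles <- c("wildtype", "control", "peg", "peg_dna", "edited")
  if (!all(metadata$role %in% roles)) {
    stop("unknown role(s): ",
         paste(setdiff(metadata$role, roles), collapse = ", "))
  }
  wt_per_group <- metadata |>
    dplyr::group_by(.data$experiment_group) |>
    dplyr::summarise(n_wt = sum(.data$role == "wildtype"), .groups = "drop")
  bad <- wt_per_group$n_wt != 1L
  if (any(bad)) {
    stop("each experiment group needs exactly one wildtype; offending: ",
         paste(wt_per_group$experiment_group[bad], collapse = ", "))
  }
  wt <- metadata[metadata$role == "wildtype", ]
  if (!all(wt$lineage_wt == wt$sample_id)) {
    stop("wildtype samples must have lineage_wt == sample_id")
  }
  joined <- dplyr::left_join(
    metadata,
    dplyr::select(wt, wt_id = "sample_id", wt_group = "experiment_group"),
    by = c(lineage_wt = "wt_id")
  )
  if (anyNA(joined$wt_group)) {
    stop("dangling lineage_wt reference(s): ",
         paste(unique(metadata$lineage_wt[is.na(joined$wt_group)]),
               collapse = ", "))
  }
  if (any(joined$wt_group != joined$experiment_group)) {
    stop("lineage_wt must refer to the wildtype of the same experiment group")
  }
  if (any(metadata$role == "edited" & is.na(metadata$nuclease_id))) {
    stop("edited samples must carry a nuclease_id")
  }
  metadata[, c("sample_id", "experiment_group", "lineage_wt", "role",
               "nuclease_id", "excluded")]
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' The default clonal-lineage study design
#'
#' Fourteen usable samples in three pedigrees: a CRISPR pedigree (WT_A with
#' four edited plants, two per guide), a TALEN pedigree (WT_B with two edited
#' plants) and a control pedigree (WT_C with two untreated regenerants, two
#' PEG-treated plants and one PEG+DNA plant). A second PEG+DNA plant is
#' present but flagged `excluded`, mirroring a contaminated library.
#'
#' @param include_excluded Keep the excluded PEG-DNA#2 row (default TRUE;
#'   excluded samples are ignored downstream anyway).
#' @return A validated metadata tibble.
#' @export
study_design_metadata <- function(include_excluded = TRUE) {
  md <- tibble::tribble(
    ~sample_id,  ~experiment_group, ~lineage_wt, ~role,      ~nuclease_id, ~excluded,
    "WT_A",      "A", "WT_A", "wildtype", NA,        FALSE,
    "CRIS1#1",   "A", "WT_A", "edited",   "sgRNA1",  FALSE,
    "CRIS1#2",   "A", "WT_A", "edited",   "sgRNA1",  FALSE,
    "CRIS2#1",   "A", "WT_A", "edited",   "sgRNA2",  FALSE,
    "CRIS2#2",   "A", "WT_A", "edited",   "sgRNA2",  FALSE,
    "WT_B",      "B", "WT_B", "wildtype", NA,        FALSE,
    "TAL#1",     "B", "WT_B", "edited",   "TALEN",   FALSE,
    "TAL#2",     "B", "WT_B", "edited",   "TALEN",   FALSE,
    "WT_C",      "C", "WT_C", "wildtype", NA,        FALSE,
    "Control#1", "C", "WT_C", "control",  NA,        FALSE,
    "Control#2", "C", "WT_C", "control",  NA,        FALSE,
    "PEG#1",     "C", "WT_C", "peg",      NA,        FALSE,
    "PEG#2",     "C", "WT_C", "peg",      NA,        FALSE,
    "PEG-DNA#1", "C", "WT_C", "peg_dna",  NA,        FALSE,
    "PEG-DNA#2", "C", "WT_C", "peg_dna",  NA,        TRUE
  )
  md$nuclease_id <- as.character(md$nuclease_id)
  if (!include_excluded) md <- md[!md$excluded, ]
  validate_metadata(md)
}
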