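#' Hard-filter variant calls
#'
#' Retains calls with `qual > 20`, `depth > 3` and `alt_depth > 1` (all
#' strict inequalities). Idempotent.
#'
#' @param calls Tibble of calls with columns `qual`, `depth`, `alt_depth`
#'   (e.g. from [variant_calls()]).
#' @param min_qual,min_depth,min_alt_depth Exclusive lower bounds.
#' @return The retained rows.
#' @export
filter_calls <- function(calls, min_qual = 20, min_depth = 3,
                         min_alt_depth = 1) {
  dplyr::filter(
    calls,
    !is.na(.data$qual) & .data$qual > min_qual,
    !is.na(.data$depth) & .data$depth > min_depth,
    !is.na(.data$alt_depth) & .data$alt_depth > min_alt_depth
  )
}

#' Haploid allele-fraction rule
#'
#' In a haploid clone a true fixed variant should be supported by (nearly)
#' all reads. Calls with `vaf >= 0.8` are treated as fixed; calls with
#' `chimera_floor <= vaf < 0.8` as chimeric (subclonal) evidence; anything
#' lower — or with zero depth — as rejected (likely false positives).
#'
#' @param vaf Numeric vector of allele fractions (`alt_depth / depth`).
#' @param depth Optional depth vector; zero or missing depth rejects.
#' @param fixed_min VAF at and above which a call is fixed.
#' @param chimera_floor Minimum VAF for chimeric evidence.
#' @return Character vector over `{"fixed_alt", "chimeric_alt", "rejected"}`.
#' @export
apply_vaf_rule <- function(vaf, depth = NULL, fixed_min = 0.8,
                           chimera_floor = 0.05) {
  state <- dplyr::case_when(
    is.na(vaf) ~ "rejected",
    vaf >= fixed_min ~ "fixed_alt",
    vaf >= chimera_floor ~ "chimeric_alt",
    TRUE ~ "rejected"
  )
  if (!is.null(depth)) {
    state[is.na(depth) | depth == 0L] <- "rejected"
  }
  state
}

#' Build the cross-sample site matrix
#'
#' Assembles the union of filtered call sites over all non-excluded samples
#' into a long site-by-sample state table. At each site every sample gets one
#' state:
#' * `fixed_alt` — filtered call with VAF >= 0.8;
#' * `chimeric_alt` — filtered call with chimera_floor <= VAF < 0.8;
#' * `ref` — no retained call and local depth > `min_depth`;
#' * `uncovered` — no retained call and depth <= `min_depth` (or unknown).
#'
#' Sites with any non-excluded sample `uncovered` are not classifiable (only
#' positions covered in all samples are considered) and are returned
#' separately as a QC sidecar.
#'
#' @param vcf_tbl Long table from [read_vcf()] or
#'   [simulate_experiment()]`$vcf` (all samples at all sites; the `gt = 0`
#'   rows supply per-sample depths at non-variant positions).
#' @param metadata Validated metadata tibble; excluded samples are dropped.
#' @param min_qual,min_depth,min_alt_depth Hard-filter bounds, as in
#'   [filter_calls()].
#' @param fixed_min,chimera_floor VAF rule bounds, as in [apply_vaf_rule()].
#' @return An object of class `variant_matrix`: a list with
#'   * `states` — long tibble (site key columns, `sample_id`, `state`,
#'     `vaf`, `depth`) over classifiable sites;
#'   * `dropped` — site-level tibble of coverage-dropped sites with the
#'     number of uncovered samples;
#'   * `samples` — the non-excluded sample ids.
#' @export
build_site_matrix <- function(vcf_tbl, metadata, min_qual = 20,
                              min_depth = 3, min_alt_depth = 1,
                              fixed_min = 0.8, chimera_floor = 0.05) {
  metadata <- validate_metadata(metadata)
  samples <- metadata$sample_id[!metadata$excluded]
  unknown <- setdiff(unique(vcf_tbl$sample_id), metadata$sample_id)
  if (length(unknown) > 0L) {
    stop("samples in calls absent from metadata: ",
         paste(unknown, collapse = ", "))
  }
  tbl <- dplyr::filter(vcf_tbl, .data$sample_id %in% samples)

  calls <- filter_calls(variant_calls(tbl), min_qual, min_depth,
                        min_alt_depth)
  calls$state <- apply_vaf_rule(calls$vaf, calls$depth, fixed_min,
                                chimera_floor)
  calls <- dplyr::filter(calls, .data$state != "rejected")

  site_cols <- c("chrom", "pos", "ref", "alt", "var_type", "size_class")
  sites <- dplyr::distinct(calls, dplyr::across(dplyr::all_of(site_cols)))
  if (nrow(sites) == 0L) {
    return(new_variant_matrix(
      states = cbind_empty_states(site_cols),
      dropped = dplyr::mutate(sites, n_uncovered = integer(0)),
      samples = samples
    ))
  }

  # full site x sample grid; fill states from calls, depths from the table
  grid <- tidyr::crossing(sites, sample_id = samples)
  depths <- dplyr::select(tbl, dplyr::all_of(site_cols), "sample_id",
                          "depth")
  grid <- dplyr::left_join(grid, depths,
                           by = c(site_cols, "sample_id"))
  grid <- dplyr::left_join(
    grid,
    dplyr::select(calls, dplyr::all_of(site_cols), "sample_id", "state",
                  "vaf"),
    by = c(site_cols, "sample_id")
  )
  grid$state <- dplyr::case_when(
    !is.na(grid$state) ~ grid$state,
    !is.na(grid$depth) & grid$depth > min_depth ~ "ref",
    TRUE ~ "uncovered"
  )

  coverage <- grid |>
    dplyr::group_by(dplyr::across(dplyr::all_of(site_cols))) |>
    dplyr::summarise(n_uncovered = sum(.data$state == "uncovered"),
                     .groups = "drop")
  dropped <- dplyr::filter(coverage, .data$n_uncovered > 0L)
  kept <- dplyr::filter(coverage, .data$n_uncovered == 0L) |>
    dplyr::select(dplyr::all_of(site_cols))
  states <- dplyr::semi_join(grid, kept, by = site_cols) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   match(.data$sample_id, samples))
  new_variant_matrix(states = states, dropped = dropped, samples = samples)
}

new_variant_matrix <- function(states, dropped, samples) {
  structure(list(states = tibble::as_tibble(states),
                 dropped = tibble::as_tibble(dropped),
                 samples = samples),
            class = "variant_matrix")
}

cbind_empty_states <- function(site_cols) {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), var_type = character(), size_class = character(),
    sample_id = character(), depth = integer(), state = character(),
    vaf = numeric()
  )
}

#' @export
print.variant_matrix <- function(x, ...) {
  n_sites <- nrow(dplyr::distinct(x$states, .data$chrom, .data$pos,
                                  .data$ref, .data$alt))
  cat(sprintf(
    "<variant_matrix> %d classifiable site(s) x %d sample(s); %d site(s) dropped for coverage\n",
    n_sites, length(x$samples), nrow(x$dropped)))
  invisible(x)
}

#' @rdname tidy_editaudit
#' @exportS3Method generics::tidy
tidy.variant_matrix <- function(x, ...) {
  x$states
}
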