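#' Attribute every classifiable site to its most likely origin
#'
#' Implements a lineage-aware decision tree over the cross-sample site
#' matrix. For each site, carriers are the samples in state `fixed_alt`
#' (chimeric states act only as evidence, never as carriers). Rules are
#' applied in precedence order — first match wins:
#'
#' 1. fixed in all non-excluded samples -> `ref_polymorphism`
#'    (wild-types-vs-reference polymorphism);
#' 2. fixed in one group's wild type and all plants derived from it, absent
#'    elsewhere -> `lineage_polymorphism` (pedigree-private);
#' 3. carried by an edited plant within its nuclease's on-target window ->
#'    `on_target`;
#' 4. carried by an edited plant within `window_bp` of a predicted
#'    off-target site for its nuclease -> `predicted_off_target_hit`;
#' 5. carried by two or more independently regenerated plants of one group,
#'    or fixed in a plant while chimeric in its matched wild type, or
#'    carried by an untreated control plant -> `spontaneous` (in vitro
#'    culture mutation);
#' 6. carried only by PEG-exposed plants (roles `peg`, `peg_dna`, `edited`)
#'    -> `treatment_associated`;
#' 7. otherwise -> `unattributed`.
#'
#' @param matrix A `variant_matrix` from [build_site_matrix()].
#' @param metadata Validated metadata tibble.
#' @param nucleases Optional named list of [crispr_nuclease()] /
#'   [talen_nuclease()] specs (names = `nuclease_id`); their `on_target`
#'   loci, widened by `on_target_pad`, are the on-target windows.
#' @param predicted_sites Optional tibble of predicted off-target sites
#'   (`chrom`, `start`, `end`, `nuclease_id`, optionally `is_on_target`,
#'   which are excluded from rule 4).
#' @param window_bp Window around predicted off-target sites for rule 4.
#' @param on_target_pad Padding of the on-target span for rule 3, in bases.
#' @return Tibble of classified sites: the site key columns plus `category`,
#'   `carriers` (comma-joined sample ids) and `evidence`.
#' @export
classify_variants <- function(matrix, metadata, nucleases = NULL,
                              predicted_sites = NULL, window_bp = 50L,
                              on_target_pad = 50L) {
  stopifnot(inherits(matrix, "variant_matrix"))
  metadata <- validate_metadata(metadata)
  md <- metadata[!metadata$excluded, ]
  if (any(md$role == "edited" & is.na(md$nuclease_id))) {
    stop("edited plant without nuclease_id")
  }
  states <- matrix$states
  site_cols <- c("chrom", "pos", "ref", "alt", "var_type", "size_class")
  sites <- dplyr::distinct(states,
                           dplyr::across(dplyr::all_of(site_cols)))
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(sites, category = character(0),
                         carriers = character(0), evidence = character(0)))
  }

  windows <- on_target_windows(nucleases, on_target_pad)
  pred <- predicted_sites
  if (!is.null(pred) && "is_on_target" %in% names(pred)) {
    pred <- dplyr::filter(pred, !.data$is_on_target)
  }

  info <- split_states_by_site(states, site_cols)
  classified <- purrr::map(info, function(s) {
    classify_one_site(s, md, windows, pred, window_bp)
  })
  out <- dplyr::bind_cols(sites, dplyr::bind_rows(classified))
  dplyr::arrange(out, .data$chrom, .data$pos, .data$ref, .data$alt)
}

split_states_by_site <- function(states, site_cols) {
  key <- interaction(states$chrom, states$pos, states$ref, states$alt,
                     drop = TRUE, lex.order = TRUE)
  # preserve site order of first appearance to align with distinct()
  split(states, factor(key, levels = unique(key)))
}

classify_one_site <- function(s, md, windows, pred, window_bp) {
  fixed <- s$sample_id[s$state == "fixed_alt"]
  chimeric <- s$sample_id[s$state == "chimeric_alt"]
  all_samples <- md$sample_id
  res <- function(category, evidence) {
    tibble::tibble(category = category,
                   carriers = paste(fixed, collapse = ","),
                   evidence = evidence)
  }

  # 1. shared by everything: polymorphism against the reference
  if (length(fixed) == length(all_samples) &&
      setequal(fixed, all_samples)) {
    return(res("ref_polymorphism", "fixed-in-all-samples"))
  }

  # 2. pedigree-private: wild type plus all its derived plants, nothing else
  for (g in unique(md$experiment_group)) {
    grp <- md$sample_id[md$experiment_group == g]
    if (length(fixed) == length(grp) && setequal(fixed, grp)) {
      return(res("lineage_polymorphism", paste0("fixed-in-group-", g)))
    }
  }

  carriers_md <- md[md$sample_id %in% fixed, ]
  edited <- carriers_md[carriers_md$role == "edited", ]
  pos0 <- s$pos[1] - 1L
  chrom <- s$chrom[1]

  # 3. on-target window of a carrying edited plant's nuclease
  if (nrow(edited) > 0L && !is.null(windows) && nrow(windows) > 0L) {
    w <- dplyr::semi_join(windows,
                          tibble::tibble(nuclease_id = edited$nuclease_id),
                          by = "nuclease_id")
    hit <- w$chrom == chrom & pos0 >= w$start & pos0 < w$end
    if (any(hit)) {
      return(res("on_target",
                 paste0("in-window-", w$nuclease_id[which(hit)[1]])))
    }
  }

  # 4. near a predicted off-target site of a carrying edited plant's nuclease
  if (nrow(edited) > 0L && !is.null(pred) && nrow(pred) > 0L) {
    p <- dplyr::semi_join(pred,
                          tibble::tibble(nuclease_id = edited$nuclease_id),
                          by = "nuclease_id")
    hit <- p$chrom == chrom & pos0 >= p$start - window_bp &
      pos0 <= p$end - 1L + window_bp
    if (any(hit)) {
      return(res("predicted_off_target_hit",
                 paste0("near-predicted-site-",
                        p$nuclease_id[which(hit)[1]])))
    }
  }

  # 5. spontaneous: independent recurrence, wild-type chimera echo, or
  #    presence in an untreated control
  plants <- carriers_md[carriers_md$role != "wildtype", ]
  shared_groups <- names(which(table(plants$experiment_group) >= 2L))
  if (length(shared_groups) > 0L) {
    flag <- if (dplyr::n_distinct(plants$experiment_group) > 1L) {
      "shared-across-treated;cross_group"
    } else {
      "shared-across-treated"
    }
    return(res("spontaneous", flag))
  }
  if (dplyr::n_distinct(plants$experiment_group) > 1L) {
    return(res("spontaneous", "shared-across-treated;cross_group"))
  }
  wt_echo <- plants$lineage_wt %in% chimeric
  if (nrow(plants) > 0L && any(wt_echo)) {
    return(res("spontaneous", "subclonal-in-wt"))
  }
  if (any(carriers_md$role == "control")) {
    return(res("spontaneous", "in-untreated-control"))
  }

  # 6. only PEG-exposed carriers
  if (nrow(carriers_md) > 0L &&
      all(carriers_md$role %in% c("peg", "peg_dna", "edited"))) {
    return(res("treatment_associated", "peg-exposed-only"))
  }

  res("unattributed", if (nrow(carriers_md) == 0L) "no-fixed-carrier"
      else "no-rule-matched")
}

on_target_windows <- function(nucleases, pad = 50L) {
  if (is.null(nucleases) || length(nucleases) == 0L) return(NULL)
  rows <- purrr::map(nucleases, function(spec) {
    if (is.null(spec$on_target)) return(NULL)
    tibble::tibble(
      nuclease_id = spec$nuclease_id,
      chrom = spec$on_target$chrom,
      start = spec$on_target$start - 1L - pad,   # to 0-based, padded
      end = spec$on_target$end + pad
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-plant mutation count table
#'
#' For each non-wildtype, non-excluded plant, counts the fixed variants it
#' carries that are not polymorphisms (categories on_target,
#' predicted_off_target_hit, spontaneous, treatment_associated,
#' unattributed), split into SNVs and InDels — the per-plant
#' "variants relative to the matched wild type" bookkeeping. Chimeric states
#' never count.
#'
#' @param classified Output of [classify_variants()].
#' @param metadata Validated metadata tibble.
#' @return Tibble with `sample_id`, `experiment_group`, `role`,
#'   `nuclease_id`, `n_snv`, `n_indel`.
#' @export
count_table <- function(classified, metadata) {
  metadata <- validate_metadata(metadata)
  plants <- metadata[!metadata$excluded & metadata$role != "wildtype", ]
  mut_cats <- c("on_target", "predicted_off_target_hit", "spontaneous",
                "treatment_associated", "unattributed")
  muts <- dplyr::filter(classified, .data$category %in% mut_cats)
  long <- if (nrow(muts) == 0L) {
    tibble::tibble(sample_id = character(), var_type = character())
  } else {
    tidyr::separate_rows(muts, "carriers", sep = ",") |>
      dplyr::rename(sample_id = "carriers") |>
      dplyr::select("sample_id", "var_type")
  }
  counts <- long |>
    dplyr::count(.data$sample_id, .data$var_type) |>
    tidyr::pivot_wider(names_from = "var_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("SNV", "InDel")) {
    if (!col %in% names(counts)) counts[[col]] <- integer(nrow(counts))
  }
  plants |>
    dplyr::select("sample_id", "experiment_group", "role", "nuclease_id") |>
    dplyr::left_join(counts, by = "sample_id") |>
    dplyr::mutate(n_snv = dplyr::coalesce(.data$SNV, 0L),
                  n_indel = dplyr::coalesce(.data$InDel, 0L)) |>
    dplyr::select("sample_id", "experiment_group", "role", "nuclease_id",
                  "n_snv", "n_indel")
}

#' Category totals over classified sites
#'
#' @param classified Output of [classify_variants()].
#' @return A list with `by_category` (tibble of per-category site counts,
#'   split by `var_type`), `total` (number of classified sites) and
#'   `not_polymorphism_or_spontaneous` (treatment_associated + unattributed,
#'   the jointly reported remainder).
#' @export
attribution_summary <- function(classified) {
  cats <- c("ref_polymorphism", "lineage_polymorphism", "on_target",
            "predicted_off_target_hit", "spontaneous",
            "treatment_associated", "unattributed")
  by_cat <- classified |>
    dplyr::count(category = factor(.data$category, levels = cats),
                 .data$var_type, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "var_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("SNV", "InDel")) {
    if (!col %in% names(by_cat)) by_cat[[col]] <- integer(nrow(by_cat))
  }
  by_cat <- by_cat |>
    dplyr::mutate(category = as.character(.data$category),
                  n = .data$SNV + .data$InDel) |>
    dplyr::select("category", "SNV", "InDel", "n")
  list(
    by_category = by_cat,
    total = nrow(classified),
    not_polymorphism_or_spontaneous = sum(
      classified$category %in% c("treatment_associated", "unattributed"))
  )
}
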