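#' Mismatch-tolerant genome search
#'
#' Finds every ungapped alignment of `query` against both strands of the
#' genome with Hamming distance at most `max_mm`. Minus-strand hits are
#' reported in plus-strand window coordinates. `N` bases in the genome never
#' match a query base, so windows containing `N` count those positions as
#' mismatches.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param query DNA string over `{A,C,G,T}`, length >= 10.
#' @param max_mm Maximum number of mismatches (must be < `nchar(query)`).
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `mismatches`, sorted by (`chrom`, `start`, `strand`).
#' @export
find_approximate_matches <- function(genome, query, max_mm) {
  genome <- as_genome(genome)
  check_dna(query, "query")
  query <- toupper(query)
  qlen <- nchar(query)
  if (qlen < 10L) stop("query must be at least 10 nt")
  max_mm <- as.integer(max_mm)
  if (max_mm < 0L || max_mm >= qlen) {
    stop("max_mm must be in [0, nchar(query) - 1]")
  }
  q_fwd <- Biostrings::DNAString(query)
  q_rev <- Biostrings::reverseComplement(q_fwd)
  hits <- purrr::map(names(genome), function(chrom) {
    subj <- genome[[chrom]]
    if (length(subj) < qlen) return(NULL)
    dplyr::bind_rows(
      match_one_strand(q_fwd, subj, chrom, "+", max_mm),
      match_one_strand(q_rev, subj, chrom, "-", max_mm)
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer()))
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

match_one_strand <- function(pattern, subject, chrom, strand, max_mm) {
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                with.indels = FALSE, fixed = TRUE)
  if (length(m) == 0L) return(NULL)
  starts <- Biostrings::start(m)
  ends <- Biostrings::end(m)
  keep <- starts >= 1L & ends <= length(subject)
  if (!any(keep)) return(NULL)
  starts <- starts[keep]
  mm <- Biostrings::neditStartingAt(pattern, subject, starting.at = starts,
                                    with.indels = FALSE, fixed = TRUE)
  tibble::tibble(chrom = chrom,
                 start = starts - 1L,
                 end = starts - 1L + length(pattern),
                 strand = strand,
                 mismatches = as.integer(mm))
}

#' Predict candidate CRISPR off-target loci
#'
#' Scans the genome for loci homologous to the full protospacer+PAM query at
#' up to `spec$max_mismatches` mismatches. By default mismatches are counted
#' uniformly over the whole query, PAM included. With `pam_aware = TRUE`
#' mismatches are counted over the 20-nt protospacer only and hits are kept
#' only when followed by an NGG PAM (any base, then GG) in the cut
#' orientation.
#'
#' @param genome Genome to scan.
#' @param spec A CRISPR [crispr_nuclease()] spec.
#' @param pam_aware Require an NGG PAM and ignore PAM positions in the
#'   mismatch count.
#' @return Tibble of sites: `chrom`, `start`, `end`, `strand`, `mismatches`,
#'   `nuclease_id`, `is_on_target`.
#' @export
predict_crispr_offtargets <- function(genome, spec, pam_aware = FALSE) {
  stopifnot(inherits(spec, "nuclease_spec"), spec$kind == "crispr")
  genome <- as_genome(genome)
  if (pam_aware) {
    hits <- find_approximate_matches(genome, spec$protospacer,
                                     spec$max_mismatches)
    hits <- keep_ngg_adjacent(hits, genome, nchar(spec$pam))
  } else {
    hits <- find_approximate_matches(genome, spec$query, spec$max_mismatches)
  }
  hits$nuclease_id <- rep(spec$nuclease_id, nrow(hits))
  hits <- flag_on_target(hits, spec)
  if (!is.null(spec$on_target) && !any(hits$is_on_target)) {
    warning("no hit overlaps the declared on-target locus for ",
            spec$nuclease_id, " (guide/genome mismatch?)")
  }
  hits
}

# keep protospacer hits whose PAM-side flank reads N followed by GG
# (+ strand: right flank NGG; - strand: left flank CCN on the plus strand)
keep_ngg_adjacent <- function(hits, genome, pam_len) {
  if (nrow(hits) == 0L) return(hits)
  ok <- logical(nrow(hits))
  new_start <- hits$start
  new_end <- hits$end
  for (i in seq_len(nrow(hits))) {
    seq <- genome[[hits$chrom[i]]]
    if (hits$strand[i] == "+") {
      s <- hits$end[i] + 1L                       # 1-based PAM start
      if (s + pam_len - 1L > length(seq)) next
      pam <- as.character(Biostrings::subseq(seq, s, s + pam_len - 1L))
      ok[i] <- grepl("GG$", pam)
      new_end[i] <- hits$end[i] + pam_len
    } else {
      e <- hits$start[i]                          # 1-based base before window
      if (e - pam_len + 1L < 1L) next
      pam <- as.character(Biostrings::subseq(seq, e - pam_len + 1L, e))
      ok[i] <- grepl("^CC", pam)
      new_start[i] <- hits$start[i] - pam_len
    }
  }
  hits$start <- new_start
  hits$end <- new_end
  hits[ok, , drop = FALSE]
}

flag_on_target <- function(hits, spec) {
  if (is.null(spec$on_target) || nrow(hits) == 0L) {
    hits$is_on_target <- rep(FALSE, nrow(hits))
    return(hits)
  }
  ot_start0 <- spec$on_target$start - 1L
  ot_end0 <- spec$on_target$end
  hits$is_on_target <- hits$chrom == spec$on_target$chrom &
    hits$start < ot_end0 & hits$end > ot_start0
  hits
}

#' Pair TALEN half-site hits under FokI spacer constraints
#'
#' A qualifying pair is an upstream half-site hit on the plus strand facing a
#' downstream half-site hit on the minus strand, on the same chromosome, with
#' the gap between their inner edges within `[spacer_min, spacer_max]`. All
#' four identity combinations (left/left, left/right, right/left,
#' right/right) are considered; each genomic pair is reported once.
#'
#' @param left_hits,right_hits Hit tables from [find_approximate_matches()]
#'   for the two half-sites (both strands each).
#' @param spacer_min,spacer_max Allowed gap in bases.
#' @return Tibble of paired sites: `chrom`, `start`, `end` (spanning both
#'   half-sites), `strand` (`"+"` by convention), `mismatches` (sum over the
#'   pair), plus `upstream_half_site`, `downstream_half_site`,
#'   `upstream_mm`, `downstream_mm`, `gap`.
#' @export
pair_talen_sites <- function(left_hits, right_hits, spacer_min = 5L,
                             spacer_max = 50L) {
  if (spacer_min > spacer_max) stop("spacer_min must be <= spacer_max")
  if (!"half_site" %in% names(left_hits)) {
    left_hits$half_site <- rep("left", nrow(left_hits))
  }
  if (!"half_site" %in% names(right_hits)) {
    right_hits$half_site <- rep("right", nrow(right_hits))
  }
  all_hits <- dplyr::bind_rows(left_hits, right_hits)
  plus <- dplyr::filter(all_hits, .data$strand == "+")
  minus <- dplyr::filter(all_hits, .data$strand == "-")
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), mismatches = integer(),
    upstream_half_site = character(), downstream_half_site = character(),
    upstream_mm = integer(), downstream_mm = integer(), gap = integer()
  )
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty)
  pairs <- dplyr::inner_join(
    dplyr::select(plus, "chrom", up_start = "start", up_end = "end",
                  upstream_mm = "mismatches", upstream_half_site = "half_site"),
    dplyr::select(minus, "chrom", dn_start = "start", dn_end = "end",
                  downstream_mm = "mismatches",
                  downstream_half_site = "half_site"),
    by = "chrom", relationship = "many-to-many"
  )
  pairs$gap <- pairs$dn_start - pairs$up_end
  pairs <- dplyr::filter(pairs, .data$gap >= spacer_min,
                         .data$gap <= spacer_max)
  if (nrow(pairs) == 0L) return(empty)
  pairs |>
    dplyr::transmute(
      chrom = .data$chrom, start = .data$up_start, end = .data$dn_end,
      strand = "+",
      mismatches = .data$upstream_mm + .data$downstream_mm,
      upstream_half_site = .data$upstream_half_site,
      downstream_half_site = .data$downstream_half_site,
      upstream_mm = .data$upstream_mm, downstream_mm = .data$downstream_mm,
      gap = .data$gap
    ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Predict candidate TALEN off-target loci
#'
#' Searches both half-sites at up to `spec$max_mismatches` mismatches each
#' and pairs the hits under the spec's spacer constraints.
#'
#' @inheritParams predict_crispr_offtargets
#' @param spec A TALEN [talen_nuclease()] spec.
#' @return Tibble of paired sites as in [pair_talen_sites()], plus
#'   `nuclease_id` and `is_on_target`.
#' @export
predict_talen_offtargets <- function(genome, spec) {
  stopifnot(inherits(spec, "nuclease_spec"), spec$kind == "talen")
  genome <- as_genome(genome)
  left_hits <- find_approximate_matches(genome, spec$left,
                                        spec$max_mismatches)
  right_hits <- find_approximate_matches(genome, spec$right,
                                         spec$max_mismatches)
  pairs <- pair_talen_sites(left_hits, right_hits,
                            spec$spacer_min, spec$spacer_max)
  pairs$nuclease_id <- rep(spec$nuclease_id, nrow(pairs))
  pairs <- flag_on_target(pairs, spec)
  if (!is.null(spec$on_target) && !any(pairs$is_on_target)) {
    warning("no TALEN pair overlaps the declared on-target locus for ",
            spec$nuclease_id)
  }
  pairs
}

#' Predict off-targets for any nuclease spec
#'
#' Dispatches to [predict_crispr_offtargets()] or
#' [predict_talen_offtargets()].
#'
#' @inheritParams predict_crispr_offtargets
#' @param ... Passed to the kind-specific predictor (e.g. `pam_aware`).
#' @export
predict_offtargets <- function(genome, spec, ...) {
  switch(spec$kind,
         crispr = predict_crispr_offtargets(genome, spec, ...),
         talen = predict_talen_offtargets(genome, spec),
         stop("unknown nuclease kind: ", spec$kind))
}

#' Intersect predicted sites with observed variants
#'
#' Returns every (site, variant) pair where the variant position falls within
#' the site span extended by `window_bp` on each side.
#'
#' @param sites Site table (`chrom`, `start`, `end`, 0-based half-open).
#' @param variants Variant table with `chrom` and 1-based `pos`.
#' @param window_bp Extension of each site span, in bases.
#' @return Tibble with the site columns (prefixed `site_`) joined to the
#'   variant columns.
#' @export
intersect_sites_with_variants <- function(sites, variants, window_bp = 50L) {
  window_bp <- as.integer(window_bp)
  site_keyed <- sites |>
    dplyr::rename(site_start = "start", site_end = "end",
                  site_strand = dplyr::any_of("strand"))
  paired <- dplyr::inner_join(site_keyed, variants, by = "chrom",
                              relationship = "many-to-many")
  dplyr::filter(
    paired,
    .data$pos - 1L >= .data$site_start - window_bp,
    .data$pos - 1L <= .data$site_end - 1L + window_bp
  )
}
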