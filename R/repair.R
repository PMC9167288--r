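#' Maximal junction microhomology of a deletion
#'
#' For a deletion of the 0-based half-open span `[del_start, del_end)` of
#' `ref_sequence`, returns the largest `m` such that either the `m` bases
#' immediately preceding the span equal the last `m` bases of the span, or
#' the first `m` bases of the span equal the `m` bases immediately following
#' it. These are the two equivalent alignments of a deletion that collapses
#' one copy of a flanking microhomology pair, the hallmark of
#' microhomology-mediated (Alt-EJ) repair. The result is capped at the
#' deletion length.
#'
#' @param ref_sequence A DNA string (character or
#'   [Biostrings::DNAString]).
#' @param del_start,del_end Deleted span, 0-based half-open, strictly inside
#'   the sequence (non-empty flank on both sides; the comparison on each side
#'   is capped at the available flank).
#' @return Integer microhomology length (>= 0).
#' @export
max_microhomology <- function(ref_sequence, del_start, del_end) {
  seq <- toupper(as.character(ref_sequence))
  n <- nchar(seq)
  del_start <- as.integer(del_start)
  del_end <- as.integer(del_end)
  d <- del_end - del_start
  if (d <= 0L) stop("deleted span must be non-empty")
  if (del_start <= 0L || del_end >= n) {
    stop("deleted span must sit strictly inside the sequence, with flanks")
  }
  deleted <- substr(seq, del_start + 1L, del_end)
  best <- 0L
  # left alignment: m bases before the span vs the last m deleted bases
  for (m in seq_len(min(d, del_start))) {
    if (substr(seq, del_start - m + 1L, del_start) ==
        substr(deleted, d - m + 1L, d)) {
      best <- max(best, m)
    }
  }
  # right alignment: first m deleted bases vs the m bases after the span
  for (m in seq_len(min(d, n - del_end))) {
    if (substr(deleted, 1L, m) ==
        substr(seq, del_end + 1L, del_end + m)) {
      best <- max(best, m)
    }
  }
  best
}

#' Classify an on-target indel by repair-pathway signature
#'
#' Deletions whose junction shows microhomology of at least `min_mh` bases
#' are compatible with microhomology-mediated alternative end joining
#' (Alt-EJ); a deletion that additionally carries a single substitution at
#' the junction is `alt_ej_with_substitution`; insertions and everything
#' else are `c_nhej_like` (classical non-homologous end joining). Complex
#' indels (both alleles longer than one base) are decomposed into a deletion
#' plus junction substitutions before classification.
#'
#' @param chrom,pos,ref,alt The variant in VCF convention: 1-based `pos`,
#'   anchor-base-included `ref`/`alt` alleles.
#' @param genome Genome containing `chrom`.
#' @param min_mh Minimum microhomology length for Alt-EJ compatibility.
#' @return A one-row tibble: `chrom`, `pos`, `ref`, `alt`, `del_start`,
#'   `del_end` (0-based half-open deleted span, NA for insertions),
#'   `mh_length`, `substitutions`, `repair_class`.
#' @export
classify_repair <- function(chrom, pos, ref, alt, genome, min_mh = 2L) {
  genome <- as_genome(genome)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (nchar(ref) == nchar(alt)) {
    stop("classify_repair expects an indel, not a substitution")
  }
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  seq <- as.character(genome[[chrom]])
  base <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                         alt = alt)

  if (nchar(alt) > nchar(ref)) {
    # net insertion: no microhomology-collapse signature
    return(dplyr::mutate(base, del_start = NA_integer_,
                         del_end = NA_integer_, mh_length = NA_integer_,
                         substitutions = NA_integer_,
                         repair_class = "c_nhej_like"))
  }

  d <- nchar(ref) - nchar(alt)
  aln <- best_deletion_alignment(ref, alt, d)
  del_start <- as.integer(pos) - 1L + aln$offset  # 0-based genomic
  del_end <- del_start + d
  mh <- max_microhomology(seq, del_start, del_end)
  repair_class <- if (aln$substitutions == 0L && mh >= min_mh) {
    "alt_ej_compatible"
  } else if (aln$substitutions <= 1L && mh >= min_mh) {
    "alt_ej_with_substitution"
  } else {
    "c_nhej_like"
  }
  dplyr::mutate(base, del_start = del_start, del_end = del_end,
                mh_length = as.integer(mh),
                substitutions = aln$substitutions,
                repair_class = repair_class)
}

# align alt against ref with one contiguous d-bp block deleted; choose the
# block offset minimising residual substitutions (ties: leftmost block after
# the anchor)
best_deletion_alignment <- function(ref, alt, d) {
  n_alt <- nchar(alt)
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  alt_chars <- strsplit(alt, "", fixed = TRUE)[[1]]
  best <- NULL
  for (offset in seq_len(n_alt)) {      # block starts after `offset` kept bases
    kept <- c(seq_len(offset),
              seq.int(offset + d + 1L, length.out = n_alt - offset))
    subs <- sum(ref_chars[kept] != alt_chars)
    if (is.null(best) || subs < best$substitutions) {
      best <- list(offset = offset, substitutions = as.integer(subs))
    }
    if (best$substitutions == 0L) break
  }
  best
}

#' Batch repair classification
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt` (indels
#'   only).
#' @inheritParams classify_repair
#' @return One row per variant, as in [classify_repair()].
#' @export
classify_repair_batch <- function(variants, genome, min_mh = 2L) {
  rows <- purrr::pmap(
    dplyr::select(variants, "chrom", "pos", "ref", "alt"),
    function(chrom, pos, ref, alt) {
      classify_repair(chrom, pos, ref, alt, genome, min_mh)
    }
  )
  dplyr::bind_rows(rows)
}
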