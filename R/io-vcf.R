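#' Read a multi-sample VCF into a tidy long table
#'
#' Parses a VCF v4.2 file whose FORMAT carries `GT`, `DP` and `AD` into a
#' long tibble with one row per (record allele, sample). Multiallelic records
#' are split into biallelic rows, alleles are parsimony-trimmed, and — when a
#' genome is supplied — indels are left-aligned, so that cross-sample site
#' matching is well defined. The variant allele fraction (`vaf`) is
#' recomputed as `alt_depth / depth`.
#'
#' Rows are emitted for every sample at every site, including samples with a
#' reference genotype (`gt = 0`): their depths are what
#' [build_site_matrix()] uses to decide covered-vs-uncovered states. Use
#' [variant_calls()] to keep only non-reference calls.
#'
#' @param path Path to a VCF file.
#' @param samples Optional character vector restricting (and ordering) the
#'   samples to read; default all samples in the file.
#' @param genome Optional genome ([Biostrings::DNAStringSet]) used to
#'   left-align indels.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `var_type` (`"SNV"`/`"InDel"`), `size_class` (`"small"`/`"large"`),
#'   `qual`, `sample_id`, `gt` (0, 1 or NA), `depth`, `alt_depth`, `vaf`.
#' @export
read_vcf <- function(path, samples = NULL, genome = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) {
    stop("malformed VCF header: expected exactly one #CHROM line")
  }
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L || cols[9] != "FORMAT") {
    stop("malformed VCF header: FORMAT and at least one sample required")
  }
  file_samples <- cols[-(1:9)]
  if (is.null(samples)) {
    samples <- file_samples
  } else if (!all(samples %in% file_samples)) {
    stop("samples not present in VCF: ",
         paste(setdiff(samples, file_samples), collapse = ", "))
  }
  sample_idx <- match(samples, file_samples)

  body <- lines[seq.int(hdr + 1L, length.out = length(lines) - hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(empty_vcf_tbl())
  }

  recs <- strsplit(body, "\t", fixed = TRUE)
  out <- vector("list", length(recs))
  n_skipped <- 0L
  for (i in seq_along(recs)) {
    f <- recs[[i]]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    i_gt <- match("GT", fmt)
    i_dp <- match("DP", fmt)
    i_ad <- match("AD", fmt)
    if (is.na(i_gt) || is.na(i_dp) || is.na(i_ad)) {
      n_skipped <- n_skipped + 1L
      next
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    geno <- strsplit(f[9 + sample_idx], ":", fixed = TRUE)
    gt_raw <- vapply(geno, function(g) g[i_gt], character(1))
    dp_raw <- vapply(geno, function(g) g[i_dp], character(1))
    ad_raw <- vapply(geno, function(g) g[i_ad], character(1))
    # haploid calls; for diploid-style GT take the first allele index
    gt_first <- sub("[/|].*$", "", gt_raw)
    gt_num <- suppressWarnings(as.integer(gt_first))
    depth <- suppressWarnings(as.integer(dp_raw))
    ad_split <- strsplit(ad_raw, ",", fixed = TRUE)
    qual <- suppressWarnings(as.numeric(f[6]))
    per_alt <- lapply(seq_along(alts), function(k) {
      alt_depth <- suppressWarnings(
        as.integer(vapply(ad_split, function(a) {
          if (length(a) >= k + 1L) a[k + 1L] else NA_character_
        }, character(1)))
      )
      tibble::tibble(
        chrom = f[1],
        pos = as.integer(f[2]),
        ref = f[4],
        alt = alts[k],
        qual = qual,
        sample_id = samples,
        gt = dplyr::case_when(
          is.na(gt_num) ~ NA_integer_,
          gt_num == k ~ 1L,
          TRUE ~ 0L
        ),
        depth = depth,
        alt_depth = alt_depth
      )
    })
    out[[i]] <- dplyr::bind_rows(per_alt)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " VCF record(s) without GT/DP/AD in FORMAT skipped")
  }
  tbl <- dplyr::bind_rows(out)
  if (nrow(tbl) == 0L) {
    return(empty_vcf_tbl())
  }
  tbl <- normalize_alleles(tbl, genome)
  tbl <- annotate_var_type(tbl)
  tbl$vaf <- ifelse(!is.na(tbl$depth) & tbl$depth > 0L,
                    tbl$alt_depth / tbl$depth, NA_real_)
  dplyr::arrange(
    tbl[, vcf_tbl_cols()],
    .data$chrom, .data$pos, .data$ref, .data$alt,
    match(.data$sample_id, samples)
  )
}

vcf_tbl_cols <- function() {
  c("chrom", "pos", "ref", "alt", "var_type", "size_class", "qual",
    "sample_id", "gt", "depth", "alt_depth", "vaf")
}

empty_vcf_tbl <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), var_type = character(), size_class = character(),
    qual = numeric(), sample_id = character(), gt = integer(),
    depth = integer(), alt_depth = integer(), vaf = numeric()
  )
}

annotate_var_type <- function(tbl) {
  tbl$var_type <- ifelse(nchar(tbl$ref) == 1L & nchar(tbl$alt) == 1L,
                         "SNV", "InDel")
  tbl$size_class <- ifelse(abs(nchar(tbl$ref) - nchar(tbl$alt)) > 50L,
                           "large", "small")
  tbl
}

#' Keep only non-reference calls
#'
#' @param vcf_tbl A long table from [read_vcf()] or
#'   [simulate_experiment()]`$vcf`.
#' @return The rows with `gt == 1`.
#' @export
variant_calls <- function(vcf_tbl) {
  dplyr::filter(vcf_tbl, !is.na(.data$gt), .data$gt == 1L)
}

# parsimony-trim (and, with a genome, left-align) ref/alt allele pairs.
# operates on the distinct (chrom,pos,ref,alt) keys, then joins back.
normalize_alleles <- function(tbl, genome = NULL) {
  seqs <- if (is.null(genome)) NULL else as.character(as_genome(genome))
  keys <- dplyr::distinct(tbl, .data$chrom, .data$pos, .data$ref, .data$alt)
  norm <- purrr::pmap(keys, function(chrom, pos, ref, alt) {
    v <- normalize_one(chrom, pos, ref, alt, seqs)
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   new_pos = v$pos, new_ref = v$ref, new_alt = v$alt)
  })
  keys <- dplyr::bind_rows(norm)
  tbl <- dplyr::left_join(tbl, keys, by = c("chrom", "pos", "ref", "alt"))
  tbl$pos <- tbl$new_pos
  tbl$ref <- tbl$new_ref
  tbl$alt <- tbl$new_alt
  tbl$new_pos <- tbl$new_ref <- tbl$new_alt <- NULL
  tbl
}

# seqs: named character vector of chromosome sequences (or NULL to skip
# left alignment)
normalize_one <- function(chrom, pos, ref, alt, seqs = NULL) {
  # trim shared suffix (keep at least one base on each allele)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim shared prefix, advancing pos
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (!is.null(seqs)) {
    if (chrom %in% names(seqs)) {
      seq <- seqs[[chrom]]
      # left-align pure indels: shift while the base before the event equals
      # the last base of the inserted/deleted run
      is_indel <- (nchar(ref) == 1L) != (nchar(alt) == 1L) ||
        nchar(ref) != nchar(alt)
      while (is_indel && pos > 1L &&
             (nchar(ref) == 1L || nchar(alt) == 1L)) {
        long <- if (nchar(ref) > nchar(alt)) ref else alt
        last <- substr(long, nchar(long), nchar(long))
        prev <- substr(seq, pos - 1L, pos - 1L)
        if (last != prev) break
        moved <- paste0(prev, substr(long, 1L, nchar(long) - 1L))
        if (nchar(ref) > nchar(alt)) {
          ref <- moved
          alt <- prev
        } else {
          alt <- moved
          ref <- prev
        }
        pos <- pos - 1L
      }
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Write a long variant table as a multi-sample VCF v4.2
#'
#' The inverse of [read_vcf()]: one record per distinct
#' (`chrom`, `pos`, `ref`, `alt`), FORMAT `GT:DP:AD` with `AD` holding
#' ref,alt read counts.
#'
#' @param vcf_tbl Long table with the [read_vcf()] columns.
#' @param path Output path.
#' @param sample_order Optional sample column order; default order of first
#'   appearance.
#' @param contigs Optional tibble (`chrom`, `length`) written as `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf_tbl, path, sample_order = NULL, contigs = NULL) {
  samples <- sample_order %||% unique(vcf_tbl$sample_id)
  if (!all(vcf_tbl$sample_id %in% samples)) {
    stop("sample_order is missing samples present in the table")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=editaudit",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,Description=',
           '"Read depth per allele">')
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contigs$chrom, contigs$length))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  if (nrow(vcf_tbl) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  per_site <- dplyr::count(vcf_tbl, .data$chrom, .data$pos, .data$ref,
                           .data$alt)
  if (any(per_site$n != length(samples))) {
    stop("write_vcf needs one row per sample at every site ",
         "(use the long table emitted by read_vcf/simulate_experiment)")
  }
  recs <- vcf_tbl |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = samples)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   .data$sample_id) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      qual = max(.data$qual, na.rm = TRUE),
      geno = paste(sprintf("%s:%s:%s,%s",
                           ifelse(is.na(.data$gt), ".", .data$gt),
                           ifelse(is.na(.data$depth), ".", .data$depth),
                           ifelse(is.na(.data$depth), ".",
                                  .data$depth -
                                    ifelse(is.na(.data$alt_depth), 0L,
                                           .data$alt_depth)),
                           ifelse(is.na(.data$alt_depth), ".",
                                  .data$alt_depth)),
                   collapse = "\t"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP:AD\t%s",
                   recs$chrom, recs$pos, recs$ref, recs$alt,
                   format(recs$qual, trim = TRUE), recs$geno)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
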