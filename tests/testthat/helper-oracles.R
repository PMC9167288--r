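# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's search/pairing code paths.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# sliding-window Hamming search over both strands of one chromosome string;
# returns 0-based half-open windows with mismatch counts
oracle_matches <- function(seq, query, max_mm, chrom = "chr1") {
  qlen <- nchar(query)
  n <- nchar(seq)
  if (n < qlen) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer()))
  }
  starts <- seq_len(n - qlen + 1L)
  windows <- substring(seq, starts, starts + qlen - 1L)
  count_mm <- function(pattern) {
    pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
    mm <- integer(length(windows))
    for (k in seq_len(qlen)) {
      mm <- mm + (substring(windows, k, k) != pc[k])
    }
    mm
  }
  mm_fwd <- count_mm(query)
  mm_rev <- count_mm(revcomp_chr(query))
  out <- dplyr::bind_rows(
    tibble::tibble(chrom = chrom, start = starts - 1L,
                   end = starts - 1L + qlen, strand = "+",
                   mismatches = mm_fwd),
    tibble::tibble(chrom = chrom, start = starts - 1L,
                   end = starts - 1L + qlen, strand = "-",
                   mismatches = mm_rev)
  )
  out <- out[out$mismatches <= max_mm, , drop = FALSE]
  dplyr::arrange(out, chrom, start, strand)
}

# brute-force double loop over all (plus hit, minus hit) combinations
oracle_pairs <- function(left_hits, right_hits, spacer_min, spacer_max) {
  left_hits$half_site <- if (nrow(left_hits)) "left" else character(0)
  right_hits$half_site <- if (nrow(right_hits)) "right" else character(0)
  hits <- rbind(left_hits, right_hits)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      a <- hits[i, ]
      b <- hits[j, ]
      if (a$strand != "+" || b$strand != "-") next
      if (a$chrom != b$chrom) next
      gap <- b$start - a$end
      if (gap < spacer_min || gap > spacer_max) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = a$chrom, start = a$start, end = b$end,
        upstream_half_site = a$half_site, downstream_half_site = b$half_site,
        gap = gap
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), upstream_half_site = character(),
                          downstream_half_site = character(),
                          gap = integer()))
  }
  dplyr::arrange(dplyr::distinct(dplyr::bind_rows(rows)),
                 chrom, start, end)
}

# plant `seq_str` into a chromosome of `genome` at 1-based pos
plant_seq <- function(genome, chrom, pos, seq_str) {
  seqs <- as.character(genome)
  substr(seqs[[chrom]], pos, pos + nchar(seq_str) - 1L) <- seq_str
  Biostrings::DNAStringSet(seqs)
}

# flip bases at the given 1-based offsets of a query (A<->C, G<->T)
mutate_query <- function(query, offsets) {
  chars <- strsplit(query, "", fixed = TRUE)[[1]]
  chars[offsets] <- chartr("ACGT", "CATG", chars[offsets])
  paste(chars, collapse = "")
}

# genome with all nuclease loci planted plus one degenerate (2-mismatch)
# copy of the sgRNA1 query on chr3, and the matching planted off-target
# deletion carried by CRIS1#1
offtarget_fixture <- function(config, copy_pos = 20001L) {
  genome <- simulate_genome(config)
  for (spec in config$nucleases) {
    genome <- plant_target_locus(genome, spec)
  }
  degenerate <- mutate_query(config$nucleases$sgRNA1$query, c(3L, 9L))
  genome <- plant_seq(genome, "chr3", copy_pos, degenerate)
  seq3 <- as.character(genome[["chr3"]])
  del_pos <- copy_pos + 10L
  planted <- tibble::tibble(
    sample_id = "CRIS1#1", chrom = "chr3", pos = del_pos,
    ref = substr(seq3, del_pos, del_pos + 4L),
    alt = substr(seq3, del_pos, del_pos)
  )
  list(genome = genome, planted = planted, copy_pos = copy_pos)
}

# tiny single-group design used where the full study design is overkill
mini_metadata <- function() {
  validate_metadata(tibble::tibble(
    sample_id = c("WT", "P1", "P2"),
    experiment_group = "G",
    lineage_wt = "WT",
    role = c("wildtype", "control", "peg"),
    nuclease_id = NA_character_,
    excluded = FALSE
  ))
}

# minimal long vcf table builder: one row per site x sample
toy_vcf_tbl <- function(sites, samples, carriers, depth = 20L, qual = 60,
                        vafs = NULL) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (s in samples) {
      carried <- s %in% carriers[[i]]
      af <- if (carried) {
        if (is.null(vafs)) 1 else vafs[[i]][[match(s, carriers[[i]])]]
      } else 0
      ad <- as.integer(round(depth * af))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = sites$chrom[i], pos = sites$pos[i], ref = sites$ref[i],
        alt = sites$alt[i], qual = qual, sample_id = s,
        gt = as.integer(carried), depth = depth, alt_depth = ad,
        vaf = ad / depth
      )
    }
  }
  tbl <- dplyr::bind_rows(rows)
  tbl$var_type <- ifelse(nchar(tbl$ref) == 1 & nchar(tbl$alt) == 1,
                         "SNV", "InDel")
  tbl$size_class <- ifelse(abs(nchar(tbl$ref) - nchar(tbl$alt)) > 50,
                           "large", "small")
  tbl
}
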