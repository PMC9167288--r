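test_that("exact and reverse-complement copies are found with the right strand", {
  set.seed(21)
  query <- random_dna(23L)
  bg <- random_dna(2000L)
  genome <- Biostrings::DNAStringSet(c(chr1 = bg))
  genome <- plant_seq(genome, "chr1", 501L, query)
  hits <- find_approximate_matches(genome, query, 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 500L)
  expect_equal(hits$end, 523L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  genome2 <- plant_seq(Biostrings::DNAStringSet(c(chr1 = bg)), "chr1", 901L,
                       revcomp_chr(query))
  hits2 <- find_approximate_matches(genome2, query, 0L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 900L)  # plus-strand window coordinates
  expect_equal(hits2$end, 923L)
})

test_that("search equals the brute-force Hamming oracle on random genomes", {
  # seeds 0-99, random 10-kb genomes, random 23-nt query, max_mm = 5
  for (seed in 0:99) {
    set.seed(seed)
    seq <- random_dna(10000L)
    query <- random_dna(23L)
    genome <- Biostrings::DNAStringSet(c(chr1 = seq))
    got <- find_approximate_matches(genome, query, 5L)
    want <- oracle_matches(seq, query, 5L)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 info = paste("seed", seed))
  }
})

test_that("N bases never match and count as mismatches", {
  set.seed(4)
  query <- random_dna(24L)
  planted <- paste0("NN", substr(query, 3L, 24L))
  seq <- paste0(random_dna(300L), planted, random_dna(300L))
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  expect_equal(nrow(find_approximate_matches(genome, query, 1L)), 0L)
  hits <- find_approximate_matches(genome, query, 2L)
  expect_equal(hits$mismatches[hits$start == 300L], 2L)
})

test_that("strand symmetry and mismatch monotonicity hold", {
  set.seed(77)
  seq <- random_dna(5000L)
  query <- random_dna(18L)
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  genome <- plant_seq(genome, "chr1", 1001L, query)
  genome <- plant_seq(genome, "chr1", 3001L, revcomp_chr(query))
  fwd <- find_approximate_matches(genome, query, 4L)
  rev <- find_approximate_matches(genome, revcomp_chr(query), 4L)
  flip <- function(s) ifelse(s == "+", "-", "+")
  expect_equal(
    dplyr::arrange(dplyr::mutate(fwd, strand = flip(strand)),
                   chrom, start, strand),
    dplyr::arrange(rev, chrom, start, strand)
  )
  for (k in 0:3) {
    a <- find_approximate_matches(genome, query, k)
    b <- find_approximate_matches(genome, query, k + 1L)
    expect_true(nrow(dplyr::anti_join(
      a, b, by = c("chrom", "start", "strand"))) == 0L)
  }
})

test_that("query longer than every chromosome yields an empty result", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGT"))
  hits <- find_approximate_matches(genome, strrep("ACGT", 5L), 2L)
  expect_equal(nrow(hits), 0L)
})

test_that("planted degenerate copies are counted correctly by the predictor", {
  cfg <- simulation_config(seed = 13L)
  spec <- cfg$nucleases$sgRNA1
  genome <- simulate_genome(cfg)
  genome <- plant_target_locus(genome, spec)
  # copies with 2, 4 and 6 mismatches: only the first two qualify at max 5
  for (p in list(list(5001L, c(2L, 9L)), list(9001L, c(1L, 5L, 12L, 19L)),
                 list(13001L, c(1L, 4L, 8L, 12L, 16L, 20L)))) {
    genome <- plant_seq(genome, "chr2", p[[1]],
                        mutate_query(spec$query, p[[2]]))
  }
  hits <- predict_crispr_offtargets(genome, spec)
  expect_equal(sum(hits$is_on_target), 1L)
  offs <- hits[!hits$is_on_target, ]
  expect_equal(nrow(offs), 2L)
  expect_equal(sort(offs$mismatches), c(2L, 4L))

  # planting then mutating 6 protospacer positions leaves no hit at max 5:
  # brute-force oracle agrees
  seq2 <- as.character(genome[["chr2"]])
  expect_equal(
    sum(oracle_matches(seq2, spec$query, 5L, chrom = "chr2")$start == 13000L),
    0L
  )
})

test_that("on-target-only genome warns when the guide is absent", {
  cfg <- simulation_config(seed = 2L)
  genome <- simulate_genome(cfg)    # nothing planted
  expect_warning(predict_crispr_offtargets(genome, cfg$nucleases$sgRNA1),
                 "on-target")
})

test_that("pam_aware mode requires NGG and ignores PAM mismatches", {
  set.seed(31)
  proto <- random_dna(20L)
  spec <- crispr_nuclease("g", proto, "TGG", max_mismatches = 2L)
  bg <- random_dna(3000L)
  genome <- Biostrings::DNAStringSet(c(chr1 = bg))
  genome <- plant_seq(genome, "chr1", 201L, paste0(proto, "AGG"))  # NGG ok
  genome <- plant_seq(genome, "chr1", 801L, paste0(proto, "ATT"))  # no PAM
  hits <- predict_crispr_offtargets(genome, spec, pam_aware = TRUE)
  expect_true(200L %in% hits$start)
  expect_false(any(hits$start == 800L))
})

test_that("TALEN pairing respects the facing-orientation spacer window", {
  # one left hit ending at 1018 (0-based half-open) and one facing right hit
  # starting at 1038: gap 20 -> one pair
  left <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1018L,
                         strand = "+", mismatches = 0L)
  right <- tibble::tibble(chrom = "chr1", start = 1038L, end = 1056L,
                          strand = "-", mismatches = 1L)
  pairs <- pair_talen_sites(left, right, 5L, 50L)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gap, 20L)
  expect_equal(pairs$start, 1000L)
  expect_equal(pairs$end, 1056L)
  expect_equal(pairs$mismatches, 1L)

  # boundary exclusion outside 5-50
  for (gap in c(4L, 51L)) {
    right_g <- dplyr::mutate(right, start = 1018L + gap,
                             end = 1018L + gap + 18L)
    expect_equal(nrow(pair_talen_sites(left, right_g, 5L, 50L)), 0L,
                 info = paste("gap", gap))
  }
  for (gap in c(5L, 50L)) {
    right_g <- dplyr::mutate(right, start = 1018L + gap,
                             end = 1018L + gap + 18L)
    expect_equal(nrow(pair_talen_sites(left, right_g, 5L, 50L)), 1L,
                 info = paste("gap", gap))
  }
})

test_that("TALEN pairing equals the brute-force double loop on random placements", {
  for (seed in c(1L, 2L, 3L)) {
    set.seed(seed)
    n <- 50L
    hits <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(5000L, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      mismatches = sample(0:5, n, replace = TRUE)
    )
    hits$end <- hits$start + 18L
    left <- hits[1:25, ]
    right <- hits[26:50, ]
    got <- pair_talen_sites(left, right, 5L, 50L)
    want <- oracle_pairs(left, right, 5L, 50L)
    expect_equal(
      as.data.frame(dplyr::select(got, chrom, start, end,
                                  upstream_half_site, downstream_half_site,
                                  gap)),
      as.data.frame(want), info = paste("seed", seed)
    )
  }
})

test_that("a planted TALEN pair is recovered exactly once with spacer 16", {
  cfg <- simulation_config(seed = 19L)
  spec <- cfg$nucleases$TALEN
  genome <- plant_target_locus(simulate_genome(cfg), spec)
  # exact search: the planted locus is the only qualifying pair
  left <- find_approximate_matches(genome, spec$left, 0L)
  right <- find_approximate_matches(genome, spec$right, 0L)
  pairs <- pair_talen_sites(left, right, spec$spacer_min, spec$spacer_max)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gap, 16L)
  expect_equal(pairs$upstream_half_site, "left")
  expect_equal(pairs$downstream_half_site, "right")
  # the full mismatch-tolerant predictor flags the same locus on-target
  all_pairs <- predict_talen_offtargets(genome, spec)
  expect_equal(sum(all_pairs$is_on_target), 1L)
  expect_true(16L %in% all_pairs$gap[all_pairs$is_on_target])
})

test_that("site-variant intersection matches the all-pairs interval oracle", {
  # boundary behaviour
  site <- tibble::tibble(chrom = "chr1", start = 100L, end = 120L,
                         strand = "+", mismatches = 0L, nuclease_id = "g")
  inside <- tibble::tibble(chrom = "chr1", pos = 111L, ref = "A", alt = "T")
  expect_equal(nrow(intersect_sites_with_variants(site, inside, 0L)), 1L)
  outside10 <- tibble::tibble(chrom = "chr1", pos = 130L, ref = "A",
                              alt = "T")
  expect_equal(nrow(intersect_sites_with_variants(site, outside10, 10L)), 1L)
  expect_equal(nrow(intersect_sites_with_variants(site, outside10, 9L)), 0L)

  # random sites and variants vs brute force
  set.seed(99)
  sites <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 30L, replace = TRUE),
    start = sample.int(2000L, 30L), strand = "+", mismatches = 0L,
    nuclease_id = "g"
  )
  sites$end <- sites$start + sample(10:40, 30L, replace = TRUE)
  variants <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 60L, replace = TRUE),
    pos = sample.int(2100L, 60L), ref = "A", alt = "T"
  )
  got <- intersect_sites_with_variants(sites, variants, 25L)
  want <- 0L
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(variants))) {
      p0 <- variants$pos[j] - 1L
      if (sites$chrom[i] == variants$chrom[j] &&
          p0 >= sites$start[i] - 25L && p0 <= sites$end[i] - 1L + 25L) {
        want <- want + 1L
      }
    }
  }
  expect_equal(nrow(got), want)
})
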