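test_that("genome simulation is deterministic with the configured lengths", {
  cfg <- simulation_config(seed = 1L,
                           chrom_lengths = c(50000L, 30000L, 20000L))
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(unname(Biostrings::width(g1)), c(50000L, 30000L, 20000L))
  expect_equal(names(g1), c("chr1", "chr2", "chr3"))
})

test_that("simulated base composition is uniform within binomial error", {
  cfg <- simulation_config(seed = 6L, n_chroms = 1L,
                           chrom_lengths = 100000L)
  g <- simulate_genome(cfg)
  freq <- Biostrings::alphabetFrequency(g[[1]])[c("A", "C", "G", "T")]
  n <- sum(freq)
  expect_equal(n, 100000L)
  # ~6 sigma band around 25% for a binomial(n, 1/4)
  half_width <- 6 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(freq - n / 4) < half_width))
})

test_that("config validation catches bad settings", {
  expect_error(simulation_config(chrom_lengths = c(500L, 2000L, 2000L)),
               ">= 1000")
  expect_error(simulation_config(n_ref_polymorphisms = -1L),
               "non-negative")
  expect_error(simulation_config(chrom_lengths = c(2000L, 2000L)),
               "n_chroms")
  expect_error(simulation_config(indel_fraction = 1.2), "probabilities")
  expect_error(simulation_config(on_target_mode = "hdr"), "on_target_mode")
})

test_that("planted loci are recovered and over-mutated copies are not", {
  cfg <- simulation_config(seed = 41L)
  spec <- cfg$nucleases$sgRNA2
  genome <- plant_target_locus(simulate_genome(cfg), spec)
  hits <- find_approximate_matches(genome, spec$query, 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, spec$on_target$start - 1L)
  # six protospacer mismatches exceed the 5-mismatch tolerance at that locus
  broken <- plant_seq(genome, spec$on_target$chrom, spec$on_target$start,
                      mutate_query(spec$query, c(1L, 4L, 8L, 11L, 15L, 19L)))
  hits5 <- find_approximate_matches(broken, spec$query, 5L)
  expect_false(any(hits5$start == spec$on_target$start - 1L))

  # too close to a chromosome end
  expect_error(plant_target_locus(genome, spec, chrom = "chr1", pos = 5L),
               "close to a chromosome end")
})

test_that("a null experiment contains only polymorphisms", {
  md <- mini_metadata()
  cfg <- simulation_config(seed = 9L, spontaneous_rate = 0, chimeric_rate = 0,
                           peg_snv_mean = 0, peg_indel_mean = 0,
                           noise_rate = 0, n_ref_polymorphisms = 25L,
                           n_lineage_polymorphisms = 10L, nucleases = list())
  sim <- simulate_experiment(cfg, metadata = md)
  expect_equal(sort(unique(sim$truth$category)),
               c("lineage_polymorphism", "ref_polymorphism"))
  # single group: lineage polymorphisms are carried by all three samples too
  expect_equal(nrow(dplyr::distinct(sim$truth, chrom, pos, ref, alt)), 35L)
})

test_that("simulation is deterministic and truth/VCF are conserved", {
  cfg <- simulation_config(seed = 5L, n_ref_polymorphisms = 40L,
                           n_lineage_polymorphisms = 10L)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$vcf, sim2$vcf)
  expect_identical(sim1$truth, sim2$truth)

  # every truth entry appears as an alt call of its carrier, and every alt
  # call traces back to a truth entry
  calls <- variant_calls(sim1$vcf)
  keys <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, x$sample_id)
  expect_setequal(keys(sim1$truth), keys(calls))
})

test_that("per-sample RNG streams leave other samples untouched when one is added", {
  md <- mini_metadata()
  md_plus <- validate_metadata(dplyr::bind_rows(
    md, tibble::tibble(sample_id = "P3", experiment_group = "G",
                       lineage_wt = "WT", role = "peg",
                       nuclease_id = NA_character_, excluded = FALSE)
  ))
  cfg <- simulation_config(seed = 11L, n_ref_polymorphisms = 20L,
                           n_lineage_polymorphisms = 5L, nucleases = list())
  t1 <- simulate_experiment(cfg, metadata = md)$truth
  t2 <- simulate_experiment(cfg, metadata = md_plus)$truth
  keys <- function(x, s) {
    x <- x[x$sample_id == s & x$category %in%
             c("spontaneous", "chimeric_spontaneous", "treatment_induced"), ]
    paste(x$chrom, x$pos, x$ref, x$alt, x$category)
  }
  for (s in c("P1", "P2")) {
    expect_setequal(keys(t1, s), keys(t2, s))
  }
})

test_that("realized induced counts converge to the configured means", {
  md <- mini_metadata()
  cfg_base <- simulation_config(seed = 1L, n_ref_polymorphisms = 0L,
                                n_lineage_polymorphisms = 0L,
                                spontaneous_rate = 0, chimeric_rate = 0,
                                peg_snv_mean = 6, peg_indel_mean = 4,
                                noise_rate = 0, nucleases = list())
  per_rep <- vapply(1:60, function(s) {
    cfg <- cfg_base
    cfg$seed <- s
    tr <- simulate_experiment(cfg, metadata = md)$truth
    sum(tr$category == "treatment_induced")  # one PEG-exposed plant (P2)
  }, numeric(1))
  mu <- 10        # peg_snv_mean + peg_indel_mean
  se <- sqrt(mu / length(per_rep))
  expect_lt(abs(mean(per_rep) - mu), 3 * se)
})

test_that("variant placement scales with chromosome length", {
  md <- mini_metadata()
  lens <- c(9000L, 3000L, 15000L, 6000L, 12000L, 1500L, 21000L, 4500L)
  rhos <- vapply(1:10, function(s) {
    cfg <- simulation_config(seed = s, n_chroms = 8L, chrom_lengths = lens,
                             n_ref_polymorphisms = 250L,
                             n_lineage_polymorphisms = 0L,
                             spontaneous_rate = 0, chimeric_rate = 0,
                             peg_snv_mean = 0, peg_indel_mean = 0,
                             noise_rate = 0, nucleases = list())
    sim <- simulate_experiment(cfg, metadata = md)
    counts <- dplyr::count(
      dplyr::distinct(sim$truth, chrom, pos, ref, alt), chrom)
    res <- chromosome_length_correlation(
      counts, chrom_lengths(sim$genome))
    res$rho
  }, numeric(1))
  expect_true(all(rhos > 0))
  expect_gt(mean(rhos), 0.7)
})

test_that("on-target edit modes have their advertised shapes", {
  cfg <- simulation_config(seed = 3L)
  spec <- cfg$nucleases$TALEN
  genome <- plant_target_locus(simulate_genome(cfg), spec)
  set.seed(30)
  ed <- simulate_on_target_edit(genome, spec, mode = "alt_ej")
  expect_gt(nchar(ed$ref), nchar(ed$alt))          # deletion
  res <- classify_repair(ed$chrom, ed$pos, ed$ref, ed$alt, genome)
  expect_gte(res$mh_length, 2L)

  ed2 <- simulate_on_target_edit(genome, spec, mode = "alt_ej_subst")
  expect_gt(nchar(ed2$alt), 1L)                    # complex indel
  res2 <- classify_repair(ed2$chrom, ed2$pos, ed2$ref, ed2$alt, genome)
  expect_equal(res2$repair_class, "alt_ej_with_substitution")
})

test_that("planted off-target entries must match the genome", {
  cfg <- simulation_config(seed = 15L, n_ref_polymorphisms = 5L,
                           n_lineage_polymorphisms = 2L)
  fix <- offtarget_fixture(cfg)
  cfg$planted_offtargets <- fix$planted
  sim <- simulate_experiment(cfg, genome = fix$genome)
  expect_true(any(sim$truth$category == "planted_off_target"))

  bad <- dplyr::mutate(fix$planted, ref = "NNNNN")
  cfg$planted_offtargets <- bad
  expect_error(simulate_experiment(cfg, genome = fix$genome),
               "does not match the genome")
})
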