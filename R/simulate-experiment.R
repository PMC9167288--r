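#' Simulate a truth-labelled editing experiment
#'
#' Generates a complete synthetic experiment emulating the study design:
#'
#' 1. reference polymorphisms present (fixed) in all samples;
#' 2. lineage polymorphisms private to each wild-type pedigree;
#' 3. per regenerated plant, Poisson-distributed fixed spontaneous mutations,
#'    each optionally echoed subclonally in the matched wild type or shared
#'    with one other plant of the same group, plus subclonal (chimeric)
#'    mutations in the plant itself;
#' 4. per PEG-exposed plant (roles `peg`, `peg_dna`, `edited`; the two PEG
#'    roles are treated identically), Poisson-distributed treatment-induced
#'    SNVs and InDels placed uniformly with per-chromosome probability
#'    proportional to length;
#' 5. one on-target edit per edited plant drawn from the
#'    microhomology-deletion repair model at its nuclease's planted locus;
#' 6. optional planted off-target variants; and
#' 7. injected low-quality noise calls.
#'
#' Depth is negative-binomial around `mean_depth`; alt read counts are
#' binomial around the true allele fraction. Every draw comes from an RNG
#' stream keyed on (`config$seed`, stream name), so runs are byte-identical
#' given the same configuration and adding a sample does not perturb the
#' events of the others.
#'
#' @param config A [simulation_config()].
#' @param genome Optional genome; by default one is simulated and all
#'   nuclease target loci are planted into it.
#' @param metadata Experimental design; defaults to
#'   [study_design_metadata()]. Excluded samples are simulated (they appear
#'   in the VCF) but ignored by downstream analysis.
#' @return An object of class `simulated_experiment`: list with `genome`,
#'   `vcf` (long table as in [read_vcf()]), `truth` (per-site per-sample
#'   true categories and allele fractions), `metadata`, `config`.
#' @export
simulate_experiment <- function(config, genome = NULL,
                                metadata = study_design_metadata()) {
  validate_simulation_config(config)
  metadata <- validate_metadata(metadata)
  nucleases <- config$nucleases

  if (is.null(genome)) {
    genome <- simulate_genome(config)
    for (spec in nucleases) {
      if (!is.null(spec$on_target)) {
        genome <- plant_target_locus(genome, spec)
      }
    }
  } else {
    genome <- as_genome(genome)
  }
  seqs <- as.character(genome)
  lens <- setNames(nchar(seqs), names(seqs))

  used <- new.env(parent = emptyenv(), hash = TRUE)
  # keep random background variants out of the on-target windows so that
  # positional attribution is unambiguous in truth
  for (spec in nucleases) {
    if (!is.null(spec$on_target)) {
      mark_used(used, spec$on_target$chrom,
                seq.int(max(1L, spec$on_target$start - 60L),
                        spec$on_target$end + 60L))
    }
  }

  events <- list()
  add <- function(site, sample_id, category, af) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      sample_id = sample_id, category = category, true_af = af,
      qual = config$true_qual
    )
  }
  af_lo <- config$chimera_af_range[1]
  af_hi <- config$chimera_af_range[2]

  # 1. polymorphisms against the reference: in every sample
  with_stream(config$seed, "ref_poly", {
    for (k in seq_len(config$n_ref_polymorphisms)) {
      site <- draw_site(seqs, lens, used, config$indel_fraction)
      add(site, metadata$sample_id, "ref_polymorphism", 1)
    }
  })

  # 2. pedigree-private polymorphisms: wild type + its derived plants
  wts <- metadata$sample_id[metadata$role == "wildtype"]
  for (wt in wts) {
    grp <- metadata$sample_id[metadata$lineage_wt == wt]
    with_stream(config$seed, paste0("lineage_", wt), {
      for (k in seq_len(config$n_lineage_polymorphisms)) {
        site <- draw_site(seqs, lens, used, config$indel_fraction)
        add(site, grp, "lineage_polymorphism", 1)
      }
    })
  }

  # 3-5. per-plant events
  plants <- metadata[metadata$role != "wildtype", ]
  for (r in seq_len(nrow(plants))) {
    p <- plants[r, ]
    peers <- setdiff(
      metadata$sample_id[metadata$experiment_group == p$experiment_group &
                           metadata$role != "wildtype"],
      p$sample_id
    )
    with_stream(config$seed, paste0("plant_", p$sample_id), {
      n_sp <- rpois(1L, config$spontaneous_rate)
      for (k in seq_len(n_sp)) {
        site <- draw_site(seqs, lens, used, config$indel_fraction)
        add(site, p$sample_id, "spontaneous", 1)
        u <- runif(1L)
        if (u < config$wt_echo_prob) {
          add(site, p$lineage_wt, "chimeric_spontaneous",
              runif(1L, af_lo, af_hi))
        } else if (u < config$wt_echo_prob + config$share_prob &&
                   length(peers) > 0L) {
          partner <- peers[sample.int(length(peers), 1L)]
          add(site, partner, "spontaneous", 1)
        }
      }
      n_ch <- rpois(1L, config$chimeric_rate)
      for (k in seq_len(n_ch)) {
        site <- draw_site(seqs, lens, used, config$indel_fraction)
        add(site, p$sample_id, "chimeric_spontaneous",
            runif(1L, af_lo, af_hi))
      }
      if (p$role %in% c("peg", "peg_dna", "edited")) {
        n_snv <- rpois(1L, config$peg_snv_mean)
        for (k in seq_len(n_snv)) {
          site <- draw_site(seqs, lens, used, 0)
          add(site, p$sample_id, "treatment_induced", 1)
        }
        n_ind <- rpois(1L, config$peg_indel_mean)
        for (k in seq_len(n_ind)) {
          site <- draw_site(seqs, lens, used, 1)
          add(site, p$sample_id, "treatment_induced", 1)
        }
      }
      if (p$role == "edited") {
        spec <- nucleases[[p$nuclease_id]]
        if (is.null(spec)) {
          stop("no nuclease spec for id ", p$nuclease_id)
        }
        edit <- simulate_on_target_edit(genome, spec,
                                        config$on_target_mode)
        add(as.list(edit), p$sample_id, "on_target", 1)
      }
    })
  }

  # 6. planted off-target variants (caller-specified, no RNG)
  if (!is.null(config$planted_offtargets)) {
    po <- config$planted_offtargets
    for (r in seq_len(nrow(po))) {
      site <- list(chrom = po$chrom[r], pos = as.integer(po$pos[r]),
                   ref = toupper(po$ref[r]), alt = toupper(po$alt[r]))
      here <- substr(seqs[[site$chrom]], site$pos,
                     site$pos + nchar(site$ref) - 1L)
      if (here != site$ref) {
        stop("planted off-target ref allele does not match the genome at ",
             site$chrom, ":", site$pos)
      }
      add(site, po$sample_id[r], "planted_off_target", 1)
    }
  }

  # 7. injected noise calls: low QUAL and low allele fraction
  for (s in metadata$sample_id) {
    with_stream(config$seed, paste0("noise_", s), {
      n_noise <- rpois(1L, config$noise_rate)
      for (k in seq_len(n_noise)) {
        site <- draw_site(seqs, lens, used, 0)
        events[[length(events) + 1L]] <- tibble::tibble(
          chrom = site$chrom, pos = site$pos, ref = site$ref,
          alt = site$alt, sample_id = s, category = "noise",
          true_af = runif(1L, 0.02, 0.3), qual = runif(1L, 0, 30)
        )
      }
    })
  }

  truth <- dplyr::bind_rows(events) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$sample_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   match(.data$sample_id, metadata$sample_id))

  vcf <- emit_reads(truth, metadata, config)
  structure(
    list(genome = genome, vcf = vcf,
         truth = dplyr::select(truth, -"qual"),
         metadata = metadata, config = config),
    class = "simulated_experiment"
  )
}

#' @export
print.simulated_experiment <- function(x, ...) {
  n_sites <- nrow(dplyr::distinct(x$truth, .data$chrom, .data$pos,
                                  .data$ref, .data$alt))
  cat(sprintf(
    "<simulated_experiment> %d sample(s), %d true site(s), %d-chromosome genome (seed %d)\n",
    nrow(x$metadata), n_sites, length(x$genome), x$config$seed))
  invisible(x)
}

# sample one variant site; is_indel is the probability of drawing an InDel
draw_site <- function(seqs, lens, used, indel_prob) {
  for (attempt in seq_len(1000L)) {
    ci <- sample.int(length(lens), 1L, prob = lens)
    chrom <- names(lens)[ci]
    len <- lens[[ci]]
    pos <- sample.int(len - 124L, 1L) + 62L
    if (!span_free(used, chrom, seq.int(pos, pos + 12L))) next
    seq <- seqs[[chrom]]
    refbase <- substr(seq, pos, pos)
    if (!refbase %in% c("A", "C", "G", "T")) next
    if (runif(1L) < indel_prob) {
      if (runif(1L) < 0.5) {
        del_len <- sample.int(8L, 1L)
        ref <- substr(seq, pos, pos + del_len)
        alt <- refbase
      } else {
        ins_len <- sample.int(4L, 1L)
        ref <- refbase
        alt <- paste0(refbase,
                      paste(sample(c("A", "C", "G", "T"), ins_len,
                                   replace = TRUE), collapse = ""))
      }
      v <- normalize_one(chrom, pos, ref, alt, seqs)
      if (!span_free(used, chrom, seq.int(v$pos, pos + 12L))) next
      mark_used(used, chrom, seq.int(v$pos, pos + 12L))
      return(list(chrom = chrom, pos = as.integer(v$pos), ref = v$ref,
                  alt = v$alt))
    }
    alt <- sample(setdiff(c("A", "C", "G", "T"), refbase), 1L)
    mark_used(used, chrom, pos)
    return(list(chrom = chrom, pos = as.integer(pos), ref = refbase,
                alt = alt))
  }
  stop("could not place a variant: requested count exceeds available ",
       "positions")
}

mark_used <- function(used, chrom, positions) {
  for (p in positions) assign(paste0(chrom, ":", p), TRUE, envir = used)
}

span_free <- function(used, chrom, positions) {
  !any(vapply(positions, function(p) {
    exists(paste0(chrom, ":", p), envir = used, inherits = FALSE)
  }, logical(1)))
}

# turn the truth table into a long VCF table with NB depth, binomial alt
# depth and per-record QUAL
emit_reads <- function(truth, metadata, config) {
  site_cols <- c("chrom", "pos", "ref", "alt")
  sites <- truth |>
    dplyr::group_by(dplyr::across(dplyr::all_of(site_cols))) |>
    dplyr::summarise(qual = max(.data$qual), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  if (nrow(sites) == 0L) return(empty_vcf_tbl())
  grid <- tidyr::crossing(sites, sample_id = metadata$sample_id) |>
    dplyr::left_join(
      dplyr::select(truth, dplyr::all_of(site_cols), "sample_id",
                    "true_af"),
      by = c(site_cols, "sample_id")
    ) |>
    dplyr::mutate(true_af = dplyr::coalesce(.data$true_af, 0)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   match(.data$sample_id, metadata$sample_id))
  with_stream(config$seed, "emit", {
    dp <- rnbinom(nrow(grid), size = config$depth_dispersion,
                  mu = config$mean_depth)
    carrier <- grid$true_af > 0
    dp[carrier] <- pmax(dp[carrier], 1L)    # a carried allele was observed
    ad <- rbinom(nrow(grid), dp, grid$true_af)
    ad[carrier] <- pmax(ad[carrier], 1L)
    grid$depth <- as.integer(dp)
    grid$alt_depth <- as.integer(ad)
  })
  grid$gt <- ifelse(grid$true_af > 0, 1L, 0L)
  grid$vaf <- ifelse(grid$depth > 0L, grid$alt_depth / grid$depth, NA_real_)
  grid <- annotate_var_type(grid)
  grid$pos <- as.integer(grid$pos)
  grid[, vcf_tbl_cols()]
}

#' Write a simulated experiment to disk
#'
#' Writes `genome.fa`, `variants.vcf`, `metadata.tsv` and `truth.tsv` into
#' `dir`.
#'
#' @param sim A `simulated_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_vcf(sim$vcf, file.path(dir, "variants.vcf"),
            sample_order = sim$metadata$sample_id,
            contigs = chrom_lengths(sim$genome))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
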