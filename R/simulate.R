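#' Configuration for a synthetic editing experiment
#'
#' Captures the generative model of the study design: three diverged clonal
#' wild-type pedigrees sharing ancestral polymorphisms against the reference,
#' clonally regenerated plants accumulating spontaneous (sometimes subclonal)
#' mutations, PEG-transfection-induced SNVs and InDels in every PEG-exposed
#' plant, one on-target edit per edited plant drawn from a
#' microhomology-deletion model, and read-depth/allele-depth noise.
#'
#' Defaults are chosen to mirror the study conditions at desk scale: a
#' 250-kb three-chromosome genome with unequal chromosome lengths (so that
#' length-proportionality of variant placement is testable), per-plant
#' PEG-induced means of 15 SNVs and 19 InDels, rare fixed spontaneous
#' mutations, sequencing depth centred on 25x with negative-binomial
#' overdispersion, and true-call quality fixed at 60 against injected noise
#' calls with quality uniform on (0, 30) so the QUAL > 20 filter boundary is
#' exercised.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_lengths Chromosome lengths in bases (all >= 1000; unequal by
#'   default).
#' @param n_ref_polymorphisms Variants shared by every sample (wild types vs
#'   reference).
#' @param n_lineage_polymorphisms Variants private to each wild-type pedigree
#'   (the wild type and all plants derived from it).
#' @param spontaneous_rate Expected fixed spontaneous mutations per
#'   regenerated plant (Poisson mean).
#' @param chimeric_rate Expected subclonal (chimeric) mutations per plant.
#' @param wt_echo_prob Probability that a plant's fixed spontaneous mutation
#'   is also present subclonally in its matched wild type.
#' @param share_prob Probability that a fixed spontaneous mutation is shared
#'   with one other independently regenerated plant of the same group.
#' @param peg_snv_mean,peg_indel_mean Expected PEG-treatment-induced SNV and
#'   InDel counts per PEG-exposed plant (roles `peg`, `peg_dna`, `edited`).
#' @param indel_fraction Proportion of InDels among polymorphisms and
#'   spontaneous mutations.
#' @param mean_depth Target sequencing depth (negative-binomial mean).
#' @param depth_dispersion Negative-binomial size parameter; smaller values
#'   give more overdispersed depth.
#' @param noise_rate Expected injected low-quality noise calls per sample.
#' @param true_qual Phred quality assigned to true variant records.
#' @param chimera_af_range Allele-fraction range for subclonal events.
#' @param seed RNG seed; every draw is keyed on (`seed`, stream name) so the
#'   run is fully reproducible and adding a sample does not perturb others.
#' @param nucleases Named list of nuclease specs used for planting target
#'   loci and drawing on-target edits.
#' @param planted_offtargets Optional tibble (`sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`) of variants planted at predicted off-target loci.
#' @param on_target_mode Repair model for on-target edits: `"alt_ej"`,
#'   `"alt_ej_subst"` or `"c_nhej"`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_chroms = 3L,
                              chrom_lengths = c(120000L, 80000L, 50000L),
                              n_ref_polymorphisms = 150L,
                              n_lineage_polymorphisms = 40L,
                              spontaneous_rate = 1.5,
                              chimeric_rate = 0.5,
                              wt_echo_prob = 0.3,
                              share_prob = 0.15,
                              peg_snv_mean = 15,
                              peg_indel_mean = 19,
                              indel_fraction = 0.4,
                              mean_depth = 25,
                              depth_dispersion = 8,
                              noise_rate = 3,
                              true_qual = 60,
                              chimera_af_range = c(0.05, 0.5),
                              seed = 1L,
                              nucleases = example_nucleases(),
                              planted_offtargets = NULL,
                              on_target_mode = "alt_ej") {
  config <- list(
    n_chroms = as.integer(n_chroms),
    chrom_lengths = as.integer(chrom_lengths),
    n_ref_polymorphisms = as.integer(n_ref_polymorphisms),
    n_lineage_polymorphisms = as.integer(n_lineage_polymorphisms),
    spontaneous_rate = spontaneous_rate,
    chimeric_rate = chimeric_rate,
    wt_echo_prob = wt_echo_prob,
    share_prob = share_prob,
    peg_snv_mean = peg_snv_mean,
    peg_indel_mean = peg_indel_mean,
    indel_fraction = indel_fraction,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    noise_rate = noise_rate,
    true_qual = true_qual,
    chimera_af_range = chimera_af_range,
    seed = as.integer(seed),
    nucleases = nucleases,
    planted_offtargets = planted_offtargets,
    on_target_mode = on_target_mode
  )
  validate_simulation_config(config)
  structure(config, class = "simulation_config")
}

validate_simulation_config <- function(config) {
  if (length(config$chrom_lengths) != config$n_chroms) {
    stop("chrom_lengths must have n_chroms entries")
  }
  if (any(config$chrom_lengths < 1000L)) {
    stop("all chromosome lengths must be >= 1000 bases")
  }
  counts <- c(config$n_ref_polymorphisms, config$n_lineage_polymorphisms)
  rates <- c(config$spontaneous_rate, config$chimeric_rate,
             config$peg_snv_mean, config$peg_indel_mean, config$noise_rate)
  if (any(counts < 0L) || any(rates < 0)) {
    stop("all counts and rates must be non-negative")
  }
  probs <- c(config$wt_echo_prob, config$share_prob, config$indel_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (config$wt_echo_prob + config$share_prob > 1) {
    stop("wt_echo_prob + share_prob must be <= 1")
  }
  if (config$mean_depth <= 0 || config$depth_dispersion <= 0) {
    stop("mean_depth and depth_dispersion must be positive")
  }
  if (!config$on_target_mode %in% c("alt_ej", "alt_ej_subst", "c_nhej")) {
    stop("on_target_mode must be alt_ej, alt_ej_subst or c_nhej")
  }
  invisible(config)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields of [simulation_config()] can be set in a YAML file;
#' unspecified fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs")
  }
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(simulation_config)),
                     c("nucleases", "planted_offtargets"))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(simulation_config, vals)
}

#' Simulate a reference genome
#'
#' I.i.d. uniform A/C/G/T chromosomes of the configured lengths, named
#' `chr1..chrN`. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(config) {
  validate_simulation_config(config)
  with_stream(config$seed, "genome", {
    seqs <- vapply(config$chrom_lengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_along(seqs))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Plant a nuclease target locus into a genome
#'
#' Writes the exact CRISPR protospacer+PAM — or the TALEN layout
#' `left + spacer + reverse_complement(right)` — into the genome at the
#' requested locus. A 3-bp microhomology pair is embedded flanking the
#' expected cut position (in the downstream flank for CRISPR, inside the
#' spacer for TALEN) so that microhomology-collapsing (Alt-EJ) repair
#' outcomes are always constructible.
#'
#' @param genome Genome to modify.
#' @param spec A nuclease spec; defaults for `chrom`/`pos` come from
#'   `spec$on_target`.
#' @param chrom,pos Target chromosome and 1-based start of the planted
#'   layout.
#' @param spacer_len TALEN spacer length in bases.
#' @return The modified genome.
#' @export
plant_target_locus <- function(genome, spec, chrom = NULL, pos = NULL,
                               spacer_len = 16L) {
  genome <- as_genome(genome)
  chrom <- chrom %||% spec$on_target$chrom
  pos <- pos %||% spec$on_target$start
  if (is.null(chrom) || is.null(pos)) {
    stop("chrom/pos required (no on_target locus on the spec)")
  }
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  seq <- as.character(genome[[chrom]])
  if (spec$kind == "crispr") {
    layout <- spec$query
    # microhomology partner: copy protospacer bases 15-17 just after the PAM
    mh_copy <- substr(spec$protospacer, 15L, 17L)
    tail_len <- 3L
  } else {
    if (spacer_len < spec$spacer_min || spacer_len > spec$spacer_max) {
      stop("spacer_len outside the spec's spacer range")
    }
    spacer_start <- pos + nchar(spec$left)
    spacer <- substr(seq, spacer_start, spacer_start + spacer_len - 1L)
    if (spacer_len >= 14L) {
      # embed a 3-bp microhomology pair straddling the spacer midpoint
      substr(spacer, 12L, 14L) <- substr(spacer, 4L, 6L)
    }
    layout <- paste0(spec$left, spacer,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(spec$right))))
    tail_len <- 0L
  }
  end <- pos + nchar(layout) - 1L + tail_len
  if (pos < 30L || end > nchar(seq) - 30L) {
    stop("locus too close to a chromosome end")
  }
  substr(seq, pos, pos + nchar(layout) - 1L) <- layout
  if (spec$kind == "crispr") {
    substr(seq, pos + 23L, pos + 25L) <- mh_copy
  }
  out <- as.character(genome)
  names(out) <- names(genome)
  out[[chrom]] <- seq
  Biostrings::DNAStringSet(out)
}

# expected blunt-cut position, 0-based (between cut0-1 and cut0)
nuclease_cut_pos <- function(spec, start0) {
  if (spec$kind == "crispr") {
    start0 + 17L                       # 3 bp upstream of the PAM
  } else {
    start0 + nchar(spec$left) + 8L     # middle of the default 16-bp spacer
  }
}

#' Draw one on-target edit from the repair model
#'
#' `alt_ej` collapses a flanking microhomology pair (>= 2 bp) across the cut
#' site into a deletion; `alt_ej_subst` additionally substitutes one retained
#' base at the junction (and verifies, by re-alignment, that the substitution
#' cannot be explained away as a shifted pure deletion); `c_nhej` produces a
#' 1-3 bp insertion or deletion at the cut without any microhomology
#' requirement. Draws consume the caller's RNG stream.
#'
#' @param genome Genome containing the planted locus.
#' @param spec Nuclease spec with an `on_target` locus.
#' @param mode One of `"alt_ej"`, `"alt_ej_subst"`, `"c_nhej"`.
#' @param search_window Bases around the cut scanned for microhomology pairs.
#' @return One-row tibble `chrom`, `pos`, `ref`, `alt` (VCF convention).
#' @export
simulate_on_target_edit <- function(genome, spec, mode = "alt_ej",
                                    search_window = 25L) {
  genome <- as_genome(genome)
  if (is.null(spec$on_target)) stop("spec has no on_target locus")
  chrom <- spec$on_target$chrom
  seq <- as.character(genome[[chrom]])
  start0 <- spec$on_target$start - 1L
  cut0 <- nuclease_cut_pos(spec, start0)

  if (mode == "c_nhej") {
    anchor1 <- cut0                     # 1-based base just before the cut
    len <- sample(1:3, 1L)
    if (runif(1) < 0.5) {
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      ref <- substr(seq, anchor1, anchor1)
      alt <- paste0(ref, ins)
    } else {
      ref <- substr(seq, anchor1, anchor1 + len)
      alt <- substr(seq, anchor1, anchor1)
    }
    return(tibble::tibble(chrom = chrom, pos = anchor1, ref = ref,
                          alt = alt))
  }

  pairs <- microhomology_pairs(seq, cut0, search_window)
  if (nrow(pairs) == 0L) {
    stop("no microhomology pair >= 2 bp within the search window around ",
         "the cut site")
  }
  best_m <- max(pairs$m)
  cand <- pairs[pairs$m == best_m, , drop = FALSE]
  pick <- cand[sample(nrow(cand), 1L), ]
  i <- pick$i
  j <- pick$j
  m <- pick$m
  anchor1 <- i + m                      # 1-based anchor before deleted span
  ref <- substr(seq, anchor1, j + m)
  alt <- substr(seq, anchor1, anchor1)
  if (mode == "alt_ej") {
    return(tibble::tibble(chrom = chrom, pos = anchor1, ref = ref,
                          alt = alt))
  }

  # alt_ej_subst: substitute the first retained base after the junction
  next_base <- substr(seq, j + m + 1L, j + m + 1L)
  for (sub in sample(setdiff(c("A", "C", "G", "T"), next_base))) {
    ref2 <- paste0(ref, next_base)
    alt2 <- paste0(alt, sub)
    aln <- best_deletion_alignment(ref2, alt2, nchar(ref2) - nchar(alt2))
    if (aln$substitutions == 1L) {
      return(tibble::tibble(chrom = chrom, pos = anchor1, ref = ref2,
                            alt = alt2))
    }
  }
  stop("could not construct an unambiguous junction substitution at ",
       chrom, ":", anchor1)
}

# all (i, j, m) with seq[i..i+m) == seq[j..j+m), i + m <= cut0 < j + m,
# j > i, within +/- window of the cut; 0-based i, j
microhomology_pairs <- function(seq, cut0, window, min_m = 2L, max_m = 6L) {
  lo <- max(0L, cut0 - window)
  hi <- min(nchar(seq), cut0 + window)
  out <- list()
  for (m in seq.int(max_m, min_m)) {
    if (cut0 - m < lo || hi - m < cut0 - m + 1L) next
    is <- seq.int(lo, cut0 - m)
    js <- seq.int(max(lo, cut0 - m + 1L), hi - m)
    left_words <- substring(seq, is + 1L, is + m)
    right_words <- substring(seq, js + 1L, js + m)
    hits <- outer(left_words, right_words, "==") &
      outer(is, js, function(a, b) b > a & a + m <= cut0 & cut0 < b + m)
    idx <- which(hits, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        i = is[idx[, 1L]], j = js[idx[, 2L]], m = m
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(i = integer(), j = integer(), m = integer()))
  }
  dplyr::bind_rows(out)
}
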