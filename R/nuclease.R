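#' Nuclease specifications
#'
#' Constructors for the two supported site-directed nucleases. A CRISPR spec
#' carries the 20-nt protospacer plus 3-nt PAM; a TALEN spec carries the two
#' half-site sequences (each written 5'->3' as its monomer reads its strand)
#' and the FokI spacer range. `on_target` optionally records the intended
#' locus as a 1-based inclusive span, used to flag the on-target hit and to
#' build on-target windows for classification.
#'
#' @param nuclease_id Identifier used throughout site tables and metadata.
#' @param protospacer 20-nt protospacer sequence (5'->3').
#' @param pam PAM sequence adjacent to the protospacer (default `"NGG"`-like
#'   concrete 3-mer; mismatches over the PAM are counted like any other
#'   position unless `pam_aware` search is requested downstream).
#' @param max_mismatches Maximum Hamming mismatches tolerated in search.
#' @param on_target Optional list `list(chrom =, start =, end =)`, 1-based
#'   inclusive.
#' @return An object of class `nuclease_spec`.
#' @export
crispr_nuclease <- function(nuclease_id, protospacer, pam,
                            max_mismatches = 5L, on_target = NULL) {
  check_dna(protospacer, "protospacer")
  check_dna(pam, "pam")
  if (nchar(protospacer) != 20L) {
    stop("protospacer must be 20 nt, got ", nchar(protospacer))
  }
  structure(
    list(nuclease_id = nuclease_id, kind = "crispr",
         protospacer = toupper(protospacer), pam = toupper(pam),
         query = toupper(paste0(protospacer, pam)),
         max_mismatches = as.integer(max_mismatches),
         on_target = on_target),
    class = "nuclease_spec"
  )
}

#' @rdname crispr_nuclease
#' @param left,right TALEN half-site sequences, 5'->3' as read by each
#'   monomer; at the target the plus strand reads
#'   `left + spacer + reverse_complement(right)`.
#' @param spacer_min,spacer_max Allowed gap (bases between the facing inner
#'   edges of the two half-site matches) for a functional FokI dimer.
#' @export
talen_nuclease <- function(nuclease_id, left, right,
                           spacer_min = 5L, spacer_max = 50L,
                           max_mismatches = 5L, on_target = NULL) {
  check_dna(left, "left half-site")
  check_dna(right, "right half-site")
  if (spacer_min > spacer_max) stop("spacer_min must be <= spacer_max")
  structure(
    list(nuclease_id = nuclease_id, kind = "talen",
         left = toupper(left), right = toupper(right),
         spacer_min = as.integer(spacer_min),
         spacer_max = as.integer(spacer_max),
         max_mismatches = as.integer(max_mismatches),
         on_target = on_target),
    class = "nuclease_spec"
  )
}

check_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) ||
      !grepl("^[ACGTacgt]+$", x)) {
    stop(what, " must be a single DNA string over {A,C,G,T}")
  }
  invisible(x)
}

#' @export
print.nuclease_spec <- function(x, ...) {
  if (x$kind == "crispr") {
    cat(sprintf("<nuclease_spec> %s: CRISPR %s|%s (max %d mismatches)\n",
                x$nuclease_id, x$protospacer, x$pam, x$max_mismatches))
  } else {
    cat(sprintf(
      "<nuclease_spec> %s: TALEN %s / %s, spacer %d-%d bp (max %d mismatches per half-site)\n",
      x$nuclease_id, x$left, x$right, x$spacer_min, x$spacer_max,
      x$max_mismatches))
  }
  invisible(x)
}

#' Example nuclease set for the synthetic study design
#'
#' Two CRISPR guides and one TALEN pair with fixed synthetic sequences
#' (chosen once; not the sequences used in any real experiment), with
#' on-target loci matching [simulation_config()] defaults. The TALEN pair
#' targets the same neighbourhood layout as a real FokI dimer: left
#' half-site, 16-bp spacer, reverse-complemented right half-site.
#'
#' @return Named list of `nuclease_spec` objects (`sgRNA1`, `sgRNA2`,
#'   `TALEN`).
#' @export
example_nucleases <- function() {
  list(
    sgRNA1 = crispr_nuclease(
      "sgRNA1",
      protospacer = "GACCTTACGGAGTCCATAGC", pam = "TGG",
      on_target = list(chrom = "chr1", start = 30001L, end = 30023L)
    ),
    sgRNA2 = crispr_nuclease(
      "sgRNA2",
      protospacer = "TTCAGGCTAACGTGATCGAA", pam = "AGG",
      on_target = list(chrom = "chr1", start = 60001L, end = 60023L)
    ),
    TALEN = talen_nuclease(
      "TALEN",
      left = "TCCAGTGCTTAGCAGAT", right = "TGACGTTCAAGGCTCAT",
      on_target = list(chrom = "chr2", start = 40001L, end = 40050L)
    )
  )
}
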