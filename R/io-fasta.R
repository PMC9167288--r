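#' Read a genome from FASTA
#'
#' Loads a (possibly line-wrapped) FASTA file as a [Biostrings::DNAStringSet],
#' the coordinate frame for all downstream sites and variants. Sequences are
#' uppercased; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(genome) == 0L) stop("FASTA file contains no records: ", path)
  # headers may carry descriptions; chromosome name = first token
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]),
               collapse = ", "))
  }
  if (any(Biostrings::width(genome) == 0L)) {
    stop("empty sequence record in FASTA")
  }
  toupper_genome(genome)
}

toupper_genome <- function(genome) {
  Biostrings::DNAStringSet(toupper(as.character(genome)))
}

#' Write a genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector of DNA sequences).
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = width)
  invisible(path)
}

# accept DNAStringSet or named character; always return uppercase DNAStringSet
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("character genome must be named")
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or named character vector")
  }
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    stop("genome chromosome names must be present and unique")
  }
  toupper_genome(genome)
}

#' Chromosome lengths of a genome
#'
#' @param genome A genome as returned by [read_fasta()] or
#'   [simulate_genome()].
#' @return A tibble with columns `chrom` and `length`.
#' @export
chrom_lengths <- function(genome) {
  genome <- as_genome(genome)
  tibble::tibble(chrom = names(genome),
                 length = Biostrings::width(genome))
}
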