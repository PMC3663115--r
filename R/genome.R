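#' Load a reference genome from FASTA
#'
#' Reads a (small) genome into memory and returns an accessor object used
#' throughout the package. All coordinates handed to [get_seq()] are 0-based
#' half-open; sequences are returned uppercase.
#'
#' @param path Path to a FASTA file. A `.fai` index is not required; the
#'   whole genome is held in memory.
#' @return An object of class `genome_ref` with elements `seqs`
#'   (a [Biostrings::DNAStringSet]) and `sizes` (named integer vector of
#'   chromosome lengths).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_ref(seqs)
}

#' Construct a genome accessor from in-memory sequences
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @return A `genome_ref` object.
#' @export
genome_ref <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("genome sequences must have unique names")
  obj <- list(seqs = seqs,
              sizes = stats::setNames(Biostrings::width(seqs), names(seqs)))
  class(obj) <- "genome_ref"
  obj
}

#' Extract a genomic subsequence
#'
#' @param genome A `genome_ref` object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase sequence string; `""` for a zero-width interval.
#' @export
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$sizes)) stop("unknown chromosome: ", chrom)
  n <- genome$sizes[[chrom]]
  if (start < 0 || end > n || start > end)
    stop(sprintf("interval [%d,%d) out of range for %s (length %d)",
                 start, end, chrom, n))
  if (start == end) return("")
  toupper(as.character(Biostrings::subseq(genome$seqs[[chrom]],
                                          start + 1L, end)))
}

#' Reverse-complement a DNA string
#'
#' @param seq Character DNA sequence (A/C/G/T/N).
#' @return Reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# vectorized reverse complement over a character vector
revcomp_many <- function(seqs) {
  if (length(seqs) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
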