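#' Local homology search and pseudogene site screening
#'
#' Candidate insertion sites that land inside an existing copy of the source
#' gene -- an annotated pseudogene, or an unannotated one detectable only by
#' sequence homology -- are artifacts of mismapping and are filtered out.
#' The same local aligner is reused to require homology between deleted
#' reference sequence and a source transcript when recovering
#' reference-genome retrocopies from deletion calls.
#'
#' @name homology
NULL

shares_seed <- function(query, target, w = 11) {
  if (nchar(query) < w || nchar(target) < w) return(FALSE)
  qk <- unique(kmerize(query, w))
  tk <- unique(kmerize(target, w))
  any(qk %in% tk)
}

#' Local alignment between two sequences
#'
#' Smith-Waterman local alignment (via \pkg{Biostrings}) preceded by an
#' 11-mer shared-seed prefilter, tried on both strands of the target. The
#' best alignment per strand is reported when it meets the identity and
#' length thresholds; unrelated random sequences yield no hit.
#'
#' @param query,target Sequences over A/C/G/T/N.
#' @param min_identity Minimum percent identity of the aligned region.
#' @param min_len Minimum aligned length (bp, alignment columns).
#' @return Data frame of hits: `q_start`, `q_end`, `t_start`, `t_end`
#'   (0-based half-open in the original sequences), `identity`, `length`,
#'   `strand`, `score`.
#' @export
local_align <- function(query, target, min_identity = 80, min_len = 100) {
  empty <- data.frame(q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      identity = numeric(0), length = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  query <- toupper(query); target <- toupper(target)
  if (nchar(query) == 0 || nchar(target) == 0) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  hits <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") target else revcomp(target)
    if (!shares_seed(query, subj)) next
    aln <- Biostrings::pairwiseAlignment(query, subj, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    if (alen < min_len) next
    ident <- 100 * Biostrings::nmatch(aln) / alen
    if (ident < min_identity) next
    qr <- aln@pattern@range
    tr <- aln@subject@range
    ts <- IRanges::start(tr) - 1L
    te <- IRanges::end(tr)
    if (strand == "-") {
      n <- nchar(target)
      tmp <- c(n - te, n - ts)
      ts <- tmp[1]; te <- tmp[2]
    }
    hits[[length(hits) + 1L]] <- data.frame(
      q_start = IRanges::start(qr) - 1L, q_end = IRanges::end(qr),
      t_start = ts, t_end = te, identity = ident, length = alen,
      strand = strand, score = Biostrings::score(aln),
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(empty)
  do.call(rbind, hits)
}

#' Screen a candidate insertion site for pre-existing pseudogene copies
#'
#' The site plus/minus `flank` bp is checked first against annotated
#' pseudogene intervals, then -- by local alignment against the source
#' gene's spliced transcript -- for an unannotated copy.
#'
#' @param call One-row call table data.frame.
#' @param pseudogene_annotations Data frame with `chrom`, `start`, `end`
#'   (0-based half-open), or NULL when no annotation library is available.
#' @param genome A `genome_ref`.
#' @param genes Named list of `gene_model` objects.
#' @param flank Window half-width around the call interval (bp).
#' @param min_identity,min_len Thresholds for declaring an unannotated copy.
#' @return `"pass"`, `"fail_annotated"` or `"fail_unannotated"`.
#' @export
screen_site <- function(call, pseudogene_annotations, genome, genes,
                        flank = 500, min_identity = 80, min_len = 100) {
  lo <- max(0, call$start - flank)
  hi <- min(genome$sizes[[call$chrom]], call$end + flank)
  pg <- pseudogene_annotations
  if (!is.null(pg) && nrow(pg) > 0) {
    overl <- pg$chrom == call$chrom & pg$start < hi & pg$end > lo
    if (any(overl)) return("fail_annotated")
  }
  gene <- genes[[call$gene_id]]
  if (!is.null(gene)) {
    site_seq <- get_seq(genome, call$chrom, lo, hi)
    tx <- spliced_transcript(gene, genome)
    hits <- local_align(site_seq, tx, min_identity = min_identity,
                        min_len = min_len)
    if (nrow(hits) > 0) return("fail_unannotated")
  }
  "pass"
}
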