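#' Breakpoint refinement from soft-clipped reads
#'
#' Reads that cross an insertion junction align up to the junction and carry
#' the inserted sequence as a soft-clipped tail. Consistent clip positions
#' pin the two junctions to base precision; the reference tract between them
#' is the target site duplication (TSD), the clipped tails at the poly-A
#' junction reveal the tail length, and the sequence flanking the 5'
#' junction carries the LINE-1 endonuclease cleavage motif (consensus
#' TTTT/AA on the nicked strand).
#'
#' @name breakpoints
NULL

# read-level scan of a BAM region; 0-based half-open coordinates
scan_reads <- function(path, region = NULL) {
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isUnmappedQuery = FALSE)
  what <- c("qname", "rname", "strand", "pos", "mapq", "cigar", "seq")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    which <- GenomicRanges::GRanges(region[[1]],
      IRanges::IRanges(as.numeric(region[[2]]) + 1, as.numeric(region[[3]])))
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = which)
  }
  res <- Rsamtools::scanBam(path, param = param)
  r <- list()
  for (fld in what)
    r[[fld]] <- combine_bam_field(res, fld)
  if (length(r$qname) == 0)
    return(data.frame(qname = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      cigar = character(0), seq = character(0),
                      clipL = integer(0), clipR = integer(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(qname = as.character(r$qname),
                   chrom = as.character(r$rname),
                   start = as.integer(r$pos) - 1L,
                   strand = as.character(r$strand),
                   mapq = as.integer(r$mapq),
                   cigar = as.character(r$cigar),
                   seq = as.character(r$seq),
                   stringsAsFactors = FALSE)
  df$end <- df$start + cigar_ref_width(df$cigar)
  df$clipL <- cigar_clip(df$cigar, "left")
  df$clipR <- cigar_clip(df$cigar, "right")
  df[!duplicated(paste(df$qname, df$cigar, df$start)), , drop = FALSE]
}

modal_position <- function(pos, min_support) {
  if (length(pos) == 0) return(NULL)
  tab <- table(pos)
  best <- max(tab)
  if (best < min_support) return(NULL)
  cand <- as.integer(names(tab)[tab == best])
  list(pos = min(cand), n = best)
}

#' Locate insertion breakpoints from soft-clipped reads
#'
#' The 5'-side breakpoint (`bp5`) is the modal aligned right edge of reads
#' whose clipped tail is on the right (reads entering the insertion from the
#' left); `bp3` is the modal aligned left edge of reads clipped on the left.
#' A breakpoint needs at least `min_support` reads agreeing at the exact
#' base. With a target site duplication of length t at site p, `bp3 = p` and
#' `bp5 = p + t`, so the two coordinates flank the duplicated tract.
#'
#' @param reads Read-level data.frame (columns `start`, `end`, `clipL`,
#'   `clipR`, `seq`) drawn from the call locus.
#' @param min_clip Minimum soft-clip length (bp) for a read to vote.
#' @param min_support Minimum reads agreeing exactly on a position.
#' @param exclude_positions Optional integer vector of positions whose clip
#'   votes are discarded (within `exclude_slop` bp). Exon boundaries of the
#'   gene annotation belong here: reads derived from any retrocopy allele of
#'   a gene soft-clip at that gene's exon edges, which would otherwise
#'   masquerade as insertion junctions near genes.
#' @param exclude_slop Exclusion half-width in bp.
#' @return List with `bp5`, `n5`, `tails5` (clipped tails at bp5), `bp3`,
#'   `n3`, `tails3`; breakpoint fields are NULL when unsupported.
#' @export
find_softclip_breakpoints <- function(reads, min_clip = 10,
                                      min_support = 2,
                                      exclude_positions = NULL,
                                      exclude_slop = 3) {
  rr <- reads[reads$clipR >= min_clip, , drop = FALSE]
  lr <- reads[reads$clipL >= min_clip, , drop = FALSE]
  if (length(exclude_positions) > 0) {
    near_excl <- function(p) vapply(p, function(x)
      any(abs(exclude_positions - x) <= exclude_slop), logical(1))
    if (nrow(rr) > 0) rr <- rr[!near_excl(rr$end), , drop = FALSE]
    if (nrow(lr) > 0) lr <- lr[!near_excl(lr$start), , drop = FALSE]
  }
  m5 <- modal_position(rr$end, min_support)
  m3 <- modal_position(lr$start, min_support)
  tails5 <- character(0)
  tails3 <- character(0)
  if (!is.null(m5)) {
    sel <- rr[rr$end == m5$pos, , drop = FALSE]
    tails5 <- substring(sel$seq, nchar(sel$seq) - sel$clipR + 1L)
  }
  if (!is.null(m3)) {
    sel <- lr[lr$start == m3$pos, , drop = FALSE]
    tails3 <- substring(sel$seq, 1L, sel$clipL)
  }
  list(bp5 = if (is.null(m5)) NULL else m5$pos,
       n5 = if (is.null(m5)) 0L else m5$n,
       tails5 = tails5,
       bp3 = if (is.null(m3)) NULL else m3$pos,
       n3 = if (is.null(m3)) 0L else m3$n,
       tails3 = tails3)
}

# consensus by per-column majority over equal-length prefixes
tail_consensus <- function(tails) {
  if (length(tails) == 0) return("")
  L <- max(nchar(tails))
  cons <- vapply(seq_len(L), function(i) {
    ch <- substr(tails, i, i)
    ch <- ch[ch != ""]
    names(sort(table(ch), decreasing = TRUE))[1]
  }, character(1))
  paste(cons, collapse = "")
}

# does the clip tail look like inserted transcript sequence? strip any
# leading poly-A/poly-T run (the tail of a reverse-oriented insert), then
# require a near-exact match of the next 12 bp inside the spliced
# transcript (either strand)
tail_matches_transcript <- function(tail, transcript, word = 12) {
  if (nchar(tail) < 8 || is.null(transcript)) return(NA)
  stripped <- sub("^A{3,}", "", sub("^T{3,}", "", tail))
  if (nchar(stripped) < 8) stripped <- tail
  w <- substr(stripped, 1, min(word, nchar(stripped)))
  for (subject in c(transcript, revcomp(transcript))) {
    hit <- Biostrings::matchPattern(w, Biostrings::DNAString(subject),
                                    max.mismatch = 1)
    if (length(hit) > 0) return(TRUE)
  }
  FALSE
}

#' Ascertain a target site duplication between two breakpoints
#'
#' Returns the reference sequence of the tract between the two junction
#' coordinates when its length is in (0, `max_tsd`] and, if clip tails and
#' the source transcript are supplied, when the 5'-junction tails actually
#' begin with inserted (transcript) sequence rather than reference
#' continuation -- guarding against coincidental breakpoint spacing.
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome of both breakpoints.
#' @param bp5,bp3 Junction coordinates from [find_softclip_breakpoints()].
#' @param max_tsd Maximum TSD length considered (bp).
#' @param tails5 Optional clipped tails at the 5' junction for confirmation.
#' @param transcript Optional spliced source transcript for confirmation.
#' @return TSD sequence string, or NULL (blunt insertion, out-of-range
#'   spacing, or failed confirmation).
#' @export
detect_tsd <- function(genome, chrom, bp5, bp3, max_tsd = 50,
                       tails5 = NULL, transcript = NULL) {
  if (is.null(bp5) || is.null(bp3)) return(NULL)
  lo <- min(bp5, bp3); hi <- max(bp5, bp3)
  if (hi - lo == 0 || hi - lo > max_tsd) return(NULL)
  tract <- get_seq(genome, chrom, lo, hi)
  if (length(tails5) > 0 && !is.null(transcript)) {
    ok <- tail_matches_transcript(tail_consensus(tails5), transcript)
    if (identical(ok, FALSE)) return(NULL)
  }
  tract
}

#' Measure the poly-A tail from junction clip tails
#'
#' Tails must be oriented reading into the insertion (i.e. starting at the
#' junction and running into the inserted sequence, reverse-complemented as
#' needed for minus-orientation insertions), so a poly-A tail appears as a
#' leading A-run. The reported length is the longest leading run containing
#' at most `max_mismatch_frac` non-A bases (and ending on an A), maximized
#' over the supplied tails; runs shorter than `min_run` report 0.
#'
#' @param tails Character vector of oriented clip tails.
#' @param min_run Minimum run length to report.
#' @param max_mismatch_frac Tolerated fraction of non-A bases in the run.
#' @return Integer poly-A length (0 when absent).
#' @export
detect_polyA <- function(tails, min_run = 5, max_mismatch_frac = 0.2) {
  if (length(tails) == 0) return(0L)
  run1 <- function(tail) {
    ch <- strsplit(tail, "")[[1]]
    if (length(ch) == 0) return(0L)
    nonA <- cumsum(ch != "A")
    ok <- which(nonA <= floor(max_mismatch_frac * seq_along(ch)) &
                  ch == "A")
    if (length(ok) == 0) 0L else max(ok)
  }
  best <- max(vapply(tails, run1, integer(1)))
  if (best < min_run) 0L else as.integer(best)
}

#' Endonuclease cleavage-site motif at the 5' junction
#'
#' Reports 4 bp on each side of the cleavage position on the strand nicked
#' by the LINE-1 endonuclease (the bottom strand for a top-strand
#' insertion), with `/` marking the scissile position. At canonical sites
#' the string starts `TTTT/AA`.
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome.
#' @param bp5 5'-junction coordinate.
#' @param insertion_strand `"+"` (nick on bottom strand) or `"-"`.
#' @return 9-character motif string (e.g. `"TTTT/AANN"`), or NULL when the
#'   window runs off the chromosome.
#' @export
en_cleavage_site <- function(genome, chrom, bp5, insertion_strand = "+") {
  if (is.null(bp5)) return(NULL)
  n <- genome$sizes[[chrom]]
  if (bp5 < 4 || bp5 + 4 > n) return(NULL)
  win <- get_seq(genome, chrom, bp5 - 4, bp5 + 4)
  if (insertion_strand == "+") {
    rc <- revcomp(win)
    paste0(substr(rc, 1, 4), "/", substr(rc, 5, 8))
  } else {
    paste0(substr(win, 1, 4), "/", substr(win, 5, 8))
  }
}

#' Annotate calls with breakpoint, TSD, poly-A and cleavage-motif evidence
#'
#' For each call, reads within `radius` bp of the call interval are pooled
#' across the supplied BAMs, soft-clip breakpoints are located, and the
#' poly-A tail is scored under both insertion orientations (the orientation
#' with the stronger tail is kept).
#'
#' @param calls Call table data.frame.
#' @param bams Character vector of indexed BAM paths.
#' @param genome A `genome_ref`.
#' @param genes Named list of `gene_model` objects (for TSD confirmation).
#' @param radius Window around the call interval (bp).
#' @param min_clip Minimum soft-clip length for breakpoint voting.
#' @return The call table with `bp5`, `bp3`, `tsd_seq`, `polyA_len` and
#'   `en_motif` filled in where evidence exists.
#' @export
annotate_breakpoints <- function(calls, bams, genome, genes, radius = 500,
                                 min_clip = 10) {
  if (nrow(calls) == 0) return(calls)
  exons <- exon_index_table(genes)
  for (i in seq_len(nrow(calls))) {
    chrom <- calls$chrom[i]
    lo <- max(0, calls$start[i] - radius)
    hi <- min(genome$sizes[[chrom]], calls$end[i] + radius)
    reads <- do.call(rbind, lapply(bams, scan_reads,
                                   region = list(chrom, lo, hi)))
    exch <- exons[exons$chrom == chrom, , drop = FALSE]
    bp <- find_softclip_breakpoints(reads, min_clip = min_clip,
                                    exclude_positions = c(exch$start,
                                                          exch$end))
    gene <- genes[[calls$gene_id[i]]]
    tx <- if (!is.null(gene)) spliced_transcript(gene, genome) else NULL
    # orientation from which junction shows the poly-A tail:
    # plus-orientation insert ends ...AAA before the right (bp3) junction;
    # read into the insertion = reversed left-clip tails. For a minus
    # orientation the tail appears as leading Ts in the bp5 tails.
    rev_chars <- function(x) vapply(x, function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1))
    pa_plus <- detect_polyA(rev_chars(bp$tails3))
    pa_minus <- detect_polyA(chartr("ACGT", "TGCA", bp$tails5))
    strand <- if (pa_minus > pa_plus) "-" else "+"
    calls$polyA_len[i] <- max(pa_plus, pa_minus)
    if (!is.null(bp$bp5)) calls$bp5[i] <- bp$bp5
    if (!is.null(bp$bp3)) calls$bp3[i] <- bp$bp3
    tsd <- detect_tsd(genome, chrom, bp$bp5, bp$bp3,
                      tails5 = bp$tails5, transcript = tx)
    if (!is.null(tsd)) calls$tsd_seq[i] <- tsd
    mot <- en_cleavage_site(genome, chrom, bp$bp5, strand)
    if (!is.null(mot)) calls$en_motif[i] <- mot
  }
  calls
}
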