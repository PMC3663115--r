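#' Exon-exon junction recovery by local assembly
#'
#' Processed retrocopies lack introns, so contigs assembled from
#' junction-informative reads at the insertion site contain exon-exon
#' junctions of the source transcript. Junction-informative reads are pairs
#' near the predicted site that are discordant, one-end-anchored, or
#' soft-clipped; they are assembled with a small de Bruijn assembler and the
#' contigs are compared against the source gene's exon sequences.
#'
#' @name junctions
NULL

#' Collect junction-informative read pairs near a call
#'
#' Keeps pairs with at least one end mapping within `radius` bp of the call
#' interval that are discordant, one-end-anchored, or soft-clipped; the mate
#' of every selected read is included even when it maps elsewhere (pairs are
#' kept whole).
#'
#' @param bam Indexed BAM path, or a pre-loaded pairs data.frame from
#'   [read_pairs()].
#' @param call One-row call table data.frame.
#' @param stats A [library_stats()] object.
#' @param radius Collection window around the call interval (bp).
#' @param sample_id Sample tag for the returned pairs.
#' @return Pairs data.frame (subset of [read_pairs()] output).
#' @export
collect_local_reads <- function(bam, call, stats, radius = 500,
                                sample_id = NA_character_) {
  pr <- if (is.data.frame(bam)) bam else
    read_pairs(bam, sample_id = sample_id)
  if (nrow(pr) == 0) return(pr)
  gap_to <- function(chrom, s, e) {
    d <- rep(Inf, length(s))
    same <- !is.na(chrom) & chrom == call$chrom
    d[same] <- pmax(0, pmax(call$start - e[same], s[same] - call$end))
    d
  }
  near <- pmin(gap_to(pr$chrom1, pr$start1, pr$end1),
               gap_to(pr$chrom2, pr$start2, pr$end2)) <= radius
  pr <- pr[near, , drop = FALSE]
  if (nrow(pr) == 0) return(pr)
  cls <- classify_pairs(pr, stats)
  keep <- cls == "discordant" | cls == "one_end_anchored" | pr$soft_clipped
  pr[keep, , drop = FALSE]
}

kmerize <- function(reads, k) {
  reads <- toupper(reads[!is.na(reads) & nchar(reads) >= k])
  if (length(reads) == 0) return(character(0))
  unlist(lapply(reads, function(r) {
    n <- nchar(r)
    substring(r, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

#' Assemble contigs from a read set with a de Bruijn graph
#'
#' Minimal double-stranded de Bruijn assembly: k-mers below `min_count`
#' occurrences (sequencing errors) and k-mers containing N are dropped,
#' maximal unbranched paths become contigs, and contigs are canonicalized
#' (lexicographic minimum of contig and reverse complement) and sorted, so
#' the result is deterministic for a given read multiset. Only contigs of at
#' least `2k - 1` bp (two overlapping k-mers' worth of sequence) are
#' reported.
#'
#' @param reads Character vector of read sequences.
#' @param k K-mer size (odd recommended).
#' @param min_count Minimum k-mer multiplicity kept (counted over both
#'   strands).
#' @return Character vector of contig sequences (possibly empty).
#' @export
assemble_contigs <- function(reads, k = 31, min_count = 2) {
  reads <- reads[!is.na(reads) & nchar(reads) > 0]
  if (length(reads) == 0) return(character(0))
  both <- c(reads, revcomp_many(reads))
  km <- kmerize(both, k)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0) return(character(0))
  tab <- table(km)
  nodes <- sort(names(tab)[tab >= min_count])
  if (length(nodes) == 0) return(character(0))
  idx <- stats::setNames(seq_along(nodes), nodes)
  bases <- c("A", "C", "G", "T")
  suff <- substring(nodes, 2L, k)
  pref <- substring(nodes, 1L, k - 1L)
  succ <- matrix(NA_integer_, nrow = length(nodes), ncol = 4)
  pred <- matrix(NA_integer_, nrow = length(nodes), ncol = 4)
  for (b in 1:4) {
    succ[, b] <- idx[paste0(suff, bases[b])]
    pred[, b] <- idx[paste0(bases[b], pref)]
  }
  outdeg <- rowSums(!is.na(succ))
  indeg <- rowSums(!is.na(pred))
  only_succ <- function(i) succ[i, which(!is.na(succ[i, ]))[1]]
  visited <- logical(length(nodes))
  contigs <- character(0)
  walk <- function(i) {
    path <- i
    visited[i] <<- TRUE
    cur <- i
    repeat {
      if (outdeg[cur] != 1) break
      nxt <- only_succ(cur)
      if (visited[nxt] || indeg[nxt] != 1) break
      visited[nxt] <<- TRUE
      path <- c(path, nxt)
      cur <- nxt
    }
    paste0(nodes[path[1]],
           paste(substring(nodes[path[-1]], k, k), collapse = ""))
  }
  starts <- which(indeg != 1)
  starts <- sort(unique(c(starts, unlist(lapply(which(outdeg > 1),
    function(i) succ[i, !is.na(succ[i, ])])))))
  for (i in starts) if (!visited[i]) contigs <- c(contigs, walk(i))
  # leftover nodes belong to simple cycles; start each at its smallest node
  for (i in seq_along(nodes)) if (!visited[i]) contigs <- c(contigs, walk(i))
  canon <- vapply(contigs, function(s) min(s, revcomp(s)), character(1),
                  USE.NAMES = FALSE)
  canon <- sort(unique(canon[nchar(canon) >= 2 * k - 1]))
  canon
}

#' Find exon-exon junctions of a source gene in a contig
#'
#' A junction (i, j) is reported when the last `min_flank` bp of exon i
#' (transcription order) are immediately followed in the contig by the first
#' `min_flank` bp of exon j, i.e. the intervening intron is absent. Both
#' contig orientations are tried; non-adjacent pairs (skipped internal
#' exons) are reported as-is.
#'
#' @param contig Contig sequence.
#' @param gene A `gene_model`.
#' @param genome A `genome_ref`.
#' @param min_flank Required exact-match flank on each side (bp).
#' @param max_mismatch Mismatches tolerated per junction pattern.
#' @return Data frame with `gene_id`, `exon_i`, `exon_j`, `offset` (0-based
#'   position of the junction pattern in the matching orientation of the
#'   contig) and `junction_seq`.
#' @export
find_spliced_junctions <- function(contig, gene, genome, min_flank = 20,
                                   max_mismatch = 0) {
  empty <- data.frame(gene_id = character(0), exon_i = integer(0),
                      exon_j = integer(0), offset = integer(0),
                      junction_seq = character(0), stringsAsFactors = FALSE)
  ne <- n_exons(gene)
  if (ne < 2 || nchar(contig) < 2 * min_flank) return(empty)
  exseq <- exon_seqs_tx(gene, genome)
  subjects <- list(Biostrings::DNAString(contig),
                   Biostrings::DNAString(revcomp(contig)))
  out <- list()
  for (i in seq_len(ne - 1)) {
    if (nchar(exseq[i]) < min_flank) next
    left <- substring(exseq[i], nchar(exseq[i]) - min_flank + 1L)
    for (j in seq(i + 1, ne)) {
      if (nchar(exseq[j]) < min_flank) next
      pat <- paste0(left, substring(exseq[j], 1L, min_flank))
      for (subject in subjects) {
        hit <- Biostrings::matchPattern(pat, subject,
                                        max.mismatch = max_mismatch)
        if (length(hit) > 0) {
          out[[length(out) + 1L]] <- data.frame(
            gene_id = gene$gene_id, exon_i = i, exon_j = j,
            offset = Biostrings::start(hit)[1] - 1L,
            junction_seq = pat, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[!duplicated(paste(res$exon_i, res$exon_j)), , drop = FALSE]
}

#' Annotate calls with recovered exon-exon junctions
#'
#' Junction-informative reads are collected around each call and assembled
#' first at `k = 31`; calls yielding no junction are retried with a more
#' sensitive `k = 21` pass. Junctions appear in the `junctions` column as
#' e.g. `"1-2;2-3"`.
#'
#' @param calls Call table data.frame.
#' @param bams Character vector of indexed BAM paths, or a list of
#'   pre-loaded pairs data.frames.
#' @param genes Named list of `gene_model` objects.
#' @param genome A `genome_ref`.
#' @param stats A [library_stats()] object (defaults to the simulator's
#'   100 bp / 500 bp library).
#' @param radius Read-collection window (bp).
#' @param kmer K-mer ladder; later values are fallbacks.
#' @param min_flank Junction flank requirement (bp).
#' @return The call table with the `junctions` column filled.
#' @export
annotate_junctions <- function(calls, bams, genes, genome,
                               stats = library_stats(100, 500, 30),
                               radius = 500, kmer = c(31, 21),
                               min_flank = 20) {
  if (nrow(calls) == 0) return(calls)
  for (i in seq_len(nrow(calls))) {
    gene <- genes[[calls$gene_id[i]]]
    if (is.null(gene)) next
    prs <- lapply(as.list(bams), collect_local_reads, call = calls[i, ],
                  stats = stats, radius = radius)
    prs <- do.call(rbind, prs)
    if (is.null(prs) || nrow(prs) == 0) next
    reads <- c(prs$seq1, prs$seq2)
    found <- NULL
    for (k in kmer) {
      contigs <- assemble_contigs(reads, k = k)
      hits <- lapply(contigs, find_spliced_junctions, gene = gene,
                     genome = genome, min_flank = min_flank)
      hits <- do.call(rbind, hits)
      if (!is.null(hits) && nrow(hits) > 0) {
        found <- hits[!duplicated(paste(hits$exon_i, hits$exon_j)), ,
                      drop = FALSE]
        break
      }
    }
    if (!is.null(found)) {
      found <- found[order(found$exon_i, found$exon_j), , drop = FALSE]
      calls$junctions[i] <- paste(paste0(found$exon_i, "-", found$exon_j),
                                  collapse = ";")
    }
  }
  calls
}

#' Write recovered junction sequences as FASTA
#'
#' @param calls Annotated call table (with `junctions` filled).
#' @param genes Named list of `gene_model` objects.
#' @param genome A `genome_ref`.
#' @param path Output FASTA path.
#' @param min_flank Flank length used when the junctions were found.
#' @return `path`, invisibly.
#' @export
write_junctions_fasta <- function(calls, genes, genome, path,
                                  min_flank = 20) {
  seqs <- character(0)
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$junctions[i]) || calls$junctions[i] == "") next
    gene <- genes[[calls$gene_id[i]]]
    exseq <- exon_seqs_tx(gene, genome)
    for (jn in strsplit(calls$junctions[i], ";")[[1]]) {
      ij <- as.integer(strsplit(jn, "-")[[1]])
      s <- paste0(substring(exseq[ij[1]],
                            nchar(exseq[ij[1]]) - min_flank + 1L),
                  substring(exseq[ij[2]], 1L, min_flank))
      nm <- sprintf("%s|%s:%d-%d|exons_%s", calls$gene_id[i],
                    calls$chrom[i], calls$start[i], calls$end[i], jn)
      seqs[nm] <- s
    }
  }
  write_fasta(seqs, path)
}
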