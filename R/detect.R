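#' Discordant-pair harvesting and insertion calling
#'
#' A retrocopy insertion leaves a characteristic footprint in paired-end
#' data: read pairs with one end in an exon of the source gene and the mate
#' at a distal locus. Mates on the 5' side of the insertion site map to the
#' plus strand and mates on the 3' side to the minus strand (FR chemistry),
#' so the minimum interval between the plus-strand group and the
#' minus-strand group brackets the insertion point.
#'
#' @name detect
NULL

default_detect_params <- function() {
  list(min_support = 8L, min_per_side = 2L, min_exons = 2L,
       window = 500L, min_mapq = 20L, distal_flank = 10000L,
       min_exon_overlap = 20L, max_side_overlap = 30L)
}

exon_index_table <- function(genes) {
  if (length(genes) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      exon_index = integer(0), span_start = integer(0),
                      span_end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(genes, function(g) {
    ex <- exons_in_tx_order(g)
    sp <- gene_span(g)
    data.frame(chrom = g$chrom, start = ex[, 1], end = ex[, 2],
               gene_id = g$gene_id, exon_index = seq_len(nrow(ex)),
               span_start = sp[1], span_end = sp[2],
               stringsAsFactors = FALSE)
  }))
}

# overlap of read intervals (0-based half-open) with exon table, requiring
# at least `minoverlap` shared bases; returns hits data.frame
exon_hits <- function(chrom, start, end, exons, minoverlap) {
  out <- data.frame(read = integer(0), exon = integer(0))
  if (length(chrom) == 0 || nrow(exons) == 0) return(out)
  for (ch in intersect(unique(chrom), unique(exons$chrom))) {
    qi <- which(chrom == ch)
    si <- which(exons$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start[qi] + 1L, end[qi]),
      IRanges::IRanges(exons$start[si] + 1L, exons$end[si]),
      minoverlap = minoverlap)
    if (length(ov) > 0)
      out <- rbind(out, data.frame(read = qi[S4Vectors::queryHits(ov)],
                                   exon = si[S4Vectors::subjectHits(ov)]))
  }
  out[order(out$read, out$exon), , drop = FALSE]
}

#' Harvest gene-anchored discordant read pairs
#'
#' Keeps discordant pairs where exactly one end overlaps an exon of a gene
#' model (by at least `min_exon_overlap` bp), both ends meet the mapping
#' quality cut-off, and the other ("distal") end lies on another chromosome
#' or outside the gene span padded by `distal_flank`.
#'
#' @param pairs Data frame from [read_pairs()] (any classification; the
#'   discordance test is applied here).
#' @param genes Named list of `gene_model` objects.
#' @param stats A [library_stats()] object.
#' @param min_mapq Minimum mapping quality for both ends.
#' @param distal_flank Padding (bp) around the gene span that the distal end
#'   must clear.
#' @param min_exon_overlap Minimum read/exon overlap (bp) for the anchor.
#' @return Data frame of discordant pairs: `sample_id`, `gene_id`,
#'   `exon_index`, anchor end columns (`exo_*`), distal end columns
#'   (`distal_*`) and `qname`.
#' @export
harvest_discordants <- function(pairs, genes, stats, min_mapq = 20,
                                distal_flank = 10000,
                                min_exon_overlap = 20) {
  empty <- data.frame(sample_id = character(0), gene_id = character(0),
                      exon_index = integer(0), exo_chrom = character(0),
                      exo_start = integer(0), exo_end = integer(0),
                      exo_strand = character(0), distal_chrom = character(0),
                      distal_start = integer(0), distal_end = integer(0),
                      distal_strand = character(0), qname = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  cls <- classify_pairs(pairs, stats)
  disc <- pairs[cls == "discordant" & pairs$mapped1 & pairs$mapped2, ,
                drop = FALSE]
  disc <- disc[disc$mapq1 >= min_mapq & disc$mapq2 >= min_mapq, ,
               drop = FALSE]
  if (nrow(disc) == 0) return(empty)
  exons <- exon_index_table(genes)
  h1 <- exon_hits(disc$chrom1, disc$start1, disc$end1, exons,
                  min_exon_overlap)
  h2 <- exon_hits(disc$chrom2, disc$start2, disc$end2, exons,
                  min_exon_overlap)
  out <- list()
  for (side in 1:2) {
    h <- if (side == 1) h1 else h2
    other_hit <- if (side == 1) h2 else h1
    if (nrow(h) == 0) next
    # keep the best (largest-overlap) exon per read-gene combination
    gidx <- exons$gene_id[h$exon]
    key <- paste(h$read, gidx)
    if (anyDuplicated(key)) {
      sfx <- if (side == 1) "1" else "2"
      ovl <- pmin(disc[[paste0("end", sfx)]][h$read], exons$end[h$exon]) -
        pmax(disc[[paste0("start", sfx)]][h$read], exons$start[h$exon])
      h <- h[order(key, -ovl), , drop = FALSE]
      h <- h[!duplicated(paste(h$read, exons$gene_id[h$exon])), ,
             drop = FALSE]
    }
    # the other end must not be exonic anywhere (exactly-one-exonic rule)
    h <- h[!(h$read %in% other_hit$read), , drop = FALSE]
    if (nrow(h) == 0) next
    e <- if (side == 1) "1" else "2"
    d <- if (side == 1) "2" else "1"
    dchrom <- disc[[paste0("chrom", d)]][h$read]
    dstart <- disc[[paste0("start", d)]][h$read]
    dend <- disc[[paste0("end", d)]][h$read]
    ex <- exons[h$exon, , drop = FALSE]
    distal_ok <- dchrom != ex$chrom |
      dend <= ex$span_start - distal_flank |
      dstart >= ex$span_end + distal_flank
    h <- h[distal_ok, , drop = FALSE]
    ex <- ex[distal_ok, , drop = FALSE]
    if (nrow(h) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      sample_id = disc$sample_id[h$read],
      gene_id = ex$gene_id,
      exon_index = ex$exon_index,
      exo_chrom = disc[[paste0("chrom", e)]][h$read],
      exo_start = disc[[paste0("start", e)]][h$read],
      exo_end = disc[[paste0("end", e)]][h$read],
      exo_strand = disc[[paste0("strand", e)]][h$read],
      distal_chrom = disc[[paste0("chrom", d)]][h$read],
      distal_start = disc[[paste0("start", d)]][h$read],
      distal_end = disc[[paste0("end", d)]][h$read],
      distal_strand = disc[[paste0("strand", d)]][h$read],
      qname = disc$qname[h$read],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$distal_chrom, res$distal_start,
                   res$distal_end, res$qname), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge per-sample discordant pairs for pooled calling
#'
#' Low-pass cohorts are analyzed by merging discordant pairs across samples
#' while keeping the sample tag, so that every genome contributing reads to
#' a call is reported as carrying the insertion.
#'
#' @param per_sample_pairs Named list (by sample ID) of data frames from
#'   [harvest_discordants()].
#' @return One merged data frame.
#' @export
pool_samples <- function(per_sample_pairs) {
  if (length(per_sample_pairs) == 0)
    return(harvest_discordants(empty_pairs_df(), list(),
                               library_stats(100, 500, 30)))
  ids <- names(per_sample_pairs)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("per-sample pair sets must be uniquely named by sample ID")
  merged <- do.call(rbind, lapply(ids, function(s) {
    df <- per_sample_pairs[[s]]
    if (nrow(df) > 0) df$sample_id <- s
    df
  }))
  rownames(merged) <- NULL
  merged
}

#' Cluster distal mappings of discordant pairs
#'
#' Single-linkage clustering per source gene and distal chromosome:
#' consecutive distal mappings (sorted by start) join the same cluster when
#' the gap between them is at most `window`.
#'
#' @param dp Data frame from [harvest_discordants()].
#' @param window Maximum joining gap in bp.
#' @return List of candidate clusters; each is a list with `chrom`,
#'   `gene_id` and `pairs` (the member rows).
#' @export
cluster_candidates <- function(dp, window = 500) {
  if (nrow(dp) == 0) return(list())
  dp <- dp[order(dp$gene_id, dp$distal_chrom, dp$distal_start,
                 dp$distal_end), , drop = FALSE]
  keys <- paste(dp$gene_id, dp$distal_chrom, sep = "\r")
  clusters <- list()
  for (k in unique(keys)) {
    sub <- dp[keys == k, , drop = FALSE]
    gap_break <- c(FALSE, sub$distal_start[-1] -
                     cummax(sub$distal_end)[-nrow(sub)] > window)
    grp <- cumsum(gap_break)
    for (g in unique(grp)) {
      mem <- sub[grp == g, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <-
        list(chrom = mem$distal_chrom[1], gene_id = mem$gene_id[1],
             pairs = mem)
    }
  }
  clusters
}

#' Emit an insertion call from a candidate cluster
#'
#' Distinct mappings are counted after de-duplicating members by (distal
#' start, distal strand), so PCR/optical duplicates count once. A call
#' requires at least `min_total` distinct mappings, at least `min_per_side`
#' on each side (plus-strand mates form the left group, minus-strand the
#' right group), anchors in at least `min_exons` distinct exons, and a clean
#' left/right separation: every left mapping must end no more than
#' `max_side_overlap` bp past any right mapping's start (target site
#' duplications let junction-proximal mates straddle slightly). The call
#' interval is the minimum interval between the two groups, clamped to zero
#' width when they touch or overlap.
#'
#' @param cluster One element of [cluster_candidates()] output.
#' @param min_total Minimum distinct supporting mappings.
#' @param min_per_side Minimum distinct mappings per side.
#' @param min_exons Minimum distinct anchor exons.
#' @param max_side_overlap Allowed left/right group overlap in bp.
#' @return A list with elements `row` (one-row call table data.frame, or
#'   NULL), `members` (de-duplicated supporting pairs), `sample_support`
#'   (named counts) and `reason` (NULL for a call, otherwise one of
#'   `"support"`, `"side_support"`, `"exon_diversity"`, `"orientation"`).
#' @export
call_insertion <- function(cluster, min_total = 8, min_per_side = 2,
                           min_exons = 2, max_side_overlap = 30) {
  p <- cluster$pairs
  dedup <- p[!duplicated(paste(p$distal_start, p$distal_strand)), ,
             drop = FALSE]
  left <- dedup[dedup$distal_strand == "+", , drop = FALSE]
  right <- dedup[dedup$distal_strand == "-", , drop = FALSE]
  fail <- function(reason) list(row = NULL, members = dedup,
                                sample_support = NULL, reason = reason)
  if (nrow(dedup) < min_total) return(fail("support"))
  if (nrow(left) < min_per_side || nrow(right) < min_per_side)
    return(fail("side_support"))
  exhit <- sort(unique(dedup$exon_index))
  if (length(exhit) < min_exons) return(fail("exon_diversity"))
  if (max(left$distal_end) > min(right$distal_start) + max_side_overlap)
    return(fail("orientation"))
  s <- max(left$distal_end)
  e <- min(right$distal_start)
  if (e < s) s <- e <- (s + e) %/% 2
  samples <- sort(unique(dedup$sample_id))
  supp <- table(factor(dedup$sample_id, levels = samples))
  row <- empty_call_table()[0, ]
  row[1, ] <- list(cluster$chrom, as.integer(s), as.integer(e),
                   cluster$gene_id, nrow(left) + nrow(right),
                   nrow(left), nrow(right),
                   paste(exhit, collapse = ","),
                   paste(samples, collapse = ","),
                   "PASS", NA_integer_, NA_integer_, "", NA_integer_,
                   "", "")
  list(row = row, members = dedup,
       sample_support = stats::setNames(as.integer(supp), names(supp)),
       reason = NULL)
}

#' Full discovery pipeline
#'
#' Runs harvest -> pool -> cluster -> call -> pseudogene screen ->
#' breakpoint/junction annotation over one or more samples and returns the
#' call table in deterministic (chrom, start, gene) order.
#'
#' @param sample_sheet Data frame (or TSV path) with columns `sample_id` and
#'   `path` (indexed BAM per sample); see [read_sample_sheet()].
#' @param genes Named list of `gene_model` objects.
#' @param genome A `genome_ref`.
#' @param stats A [library_stats()] object.
#' @param params Optional named list overriding [default_detect_params()].
#' @param pseudogenes Optional data.frame of annotated pseudogene intervals
#'   (`chrom`, `start`, `end`) for the homology screen.
#' @param annotate Add breakpoint/TSD/poly-A/junction evidence columns
#'   (requires the BAMs to be indexed).
#' @param verbose Log per-stage counts to stderr.
#' @return Call table data.frame; attribute `"audit"` holds the
#'   de-duplicated member pairs per emitted call.
#' @export
discover <- function(sample_sheet, genes, genome, stats, params = list(),
                     pseudogenes = NULL, annotate = TRUE, verbose = FALSE) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  if (anyDuplicated(sample_sheet$sample_id)) stop("duplicate sample IDs")
  prm <- utils::modifyList(default_detect_params(), params)
  log <- function(...) if (verbose) message(sprintf(...))
  per_sample <- list()
  raw_pairs <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    sid <- sample_sheet$sample_id[i]
    pr <- read_pairs(sample_sheet$path[i], sample_id = sid)
    raw_pairs[[sid]] <- pr
    dp <- harvest_discordants(pr, genes, stats,
                              min_mapq = prm$min_mapq,
                              distal_flank = prm$distal_flank,
                              min_exon_overlap = prm$min_exon_overlap)
    log("sample %s: %d pairs, %d gene-anchored discordant", sid, nrow(pr),
        nrow(dp))
    per_sample[[sid]] <- dp
  }
  pooled <- pool_samples(per_sample)
  clusters <- cluster_candidates(pooled, window = prm$window)
  log("%d candidate clusters", length(clusters))
  rows <- list(); audit <- list()
  for (cl in clusters) {
    res <- call_insertion(cl, min_total = prm$min_support,
                          min_per_side = prm$min_per_side,
                          min_exons = prm$min_exons,
                          max_side_overlap = prm$max_side_overlap)
    if (is.null(res$row)) next
    rows[[length(rows) + 1L]] <- res$row
    audit[[length(audit) + 1L]] <- res$members
  }
  if (length(rows) == 0) {
    out <- empty_call_table()
    attr(out, "audit") <- list()
    return(out)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  # pseudogene / local homology screen
  for (i in seq_len(nrow(calls))) {
    st <- screen_site(calls[i, ], pseudogenes, genome, genes)
    if (st != "pass") calls$filter_status[i] <- paste0("FILTERED_", st)
  }
  log("%d calls, %d pass homology screen", nrow(calls),
      sum(calls$filter_status == "PASS"))
  if (annotate) {
    calls <- annotate_breakpoints(calls, sample_sheet$path, genome, genes)
    calls <- annotate_junctions(calls, raw_pairs, genes, genome,
                                stats = stats)
  }
  ord <- order(calls$chrom, calls$start, calls$gene_id)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "audit") <- audit[ord]
  calls
}
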