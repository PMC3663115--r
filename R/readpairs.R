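#' Sequencing library statistics
#'
#' Describes an Illumina-style forward-reverse (FR) paired-end library.
#' `median_insert` is the median outer fragment span (leftmost mapped base of
#' one read to rightmost mapped base of its mate); for 100 bp ends with a
#' 300 bp unsequenced middle this is 500 bp.
#'
#' @param read_length Read length in bp (> 0).
#' @param median_insert Median outer fragment span in bp (>= 2 * read_length).
#' @param insert_sd Standard deviation of the fragment span in bp.
#' @param orientation Only `"FR"` (forward-reverse) is supported.
#' @return A `library_stats` object.
#' @export
library_stats <- function(read_length, median_insert, insert_sd,
                          orientation = "FR") {
  if (read_length <= 0) stop("read_length must be positive")
  if (median_insert < 2 * read_length)
    stop("median_insert must be at least twice the read length")
  if (!identical(orientation, "FR"))
    stop("only FR (forward-reverse) libraries are supported")
  structure(list(read_length = as.integer(read_length),
                 median_insert = as.numeric(median_insert),
                 insert_sd = as.numeric(insert_sd),
                 orientation = "FR"),
            class = "library_stats")
}

# combine one scanBam field across regions, flattening XStringSet to
# character so downstream data.frames hold plain strings
combine_bam_field <- function(res, fld) {
  vals <- lapply(res, function(x) {
    v <- x[[fld]]
    if (inherits(v, "XStringSet")) as.character(v) else v
  })
  do.call(c, vals)
}

# CIGAR helpers: reference-consumed width and terminal soft-clip lengths.
cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) return(list(len = integer(0), op = character(0)))
  tok <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", tok)),
       op = sub("^\\d+", "", tok))
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_clip <- function(cigar, side = c("left", "right")) {
  side <- match.arg(side)
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- cigar_ops(cg)
    op <- ops$op[ops$op != "H"]
    len <- ops$len[ops$op != "H"]
    if (length(op) == 0) return(0L)
    i <- if (side == "left") 1L else length(op)
    if (op[i] == "S") len[i] else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Read paired-end alignments from a BAM file
#'
#' Reunites primary alignments by query name and returns one row per read
#' pair with both ends side by side. Secondary, supplementary and
#' duplicate-flagged alignments are dropped so that support counting sees
#' each physical fragment once. SAM 1-based starts are converted to 0-based
#' half-open intervals at this boundary.
#'
#' @param path Indexed, coordinate-sorted BAM file.
#' @param region Optional `c(chrom, start, end)` (0-based half-open) limiting
#'   the scan; requires the index.
#' @param sample_id Sample identifier attached to every pair.
#' @return A data.frame with one row per pair: `qname`, `sample_id`, per-end
#'   columns (`chrom1`, `start1`, `end1`, `strand1`, `mapq1`, `cigar1`,
#'   `seq1`, `clipL1`, `clipR1`, `mapped1`, and the same with suffix 2), and
#'   flags `mate_unmapped` (exactly one end mapped) and `soft_clipped`.
#' @export
read_pairs <- function(path, region = NULL, sample_id = NA_character_) {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    if (!file.exists(paste0(path, ".bai")))
      stop("region query requires a BAM index (.bai) for ", path)
    which <- GenomicRanges::GRanges(region[[1]],
      IRanges::IRanges(as.numeric(region[[2]]) + 1, as.numeric(region[[3]])))
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = which)
  }
  res <- Rsamtools::scanBam(path, param = param)
  r <- list()
  for (fld in what)
    r[[fld]] <- combine_bam_field(res, fld)
  n <- length(r$qname)
  if (n == 0) return(empty_pairs_df())
  df <- data.frame(
    qname = as.character(r$qname),
    flag = as.integer(r$flag),
    chrom = as.character(r$rname),
    strand = as.character(r$strand),
    start = as.integer(r$pos) - 1L,
    mapq = as.integer(r$mapq),
    cigar = as.character(r$cigar),
    seq = as.character(r$seq),
    stringsAsFactors = FALSE)
  df$mapped <- bitwAnd(df$flag, 4L) == 0L
  df$start[!df$mapped] <- NA_integer_
  df$chrom[!df$mapped] <- NA_character_
  df$strand[!df$mapped] <- NA_character_
  df$end <- df$start + cigar_ref_width(df$cigar)
  df$clipL <- cigar_clip(df$cigar, "left")
  df$clipR <- cigar_clip(df$cigar, "right")
  df$is_first <- bitwAnd(df$flag, 64L) != 0L
  # one row per qname and mate rank; drop stray duplicates defensively
  df <- df[!duplicated(paste(df$qname, df$is_first)), , drop = FALSE]
  pair_up_reads(df, sample_id)
}

pair_up_reads <- function(df, sample_id) {
  a <- df[df$is_first, , drop = FALSE]
  b <- df[!df$is_first, , drop = FALSE]
  qn <- union(a$qname, b$qname)
  ia <- match(qn, a$qname)
  ib <- match(qn, b$qname)
  end_cols <- function(side, idx) {
    cols <- c("chrom", "start", "end", "strand", "mapq", "cigar", "seq",
              "clipL", "clipR", "mapped")
    out <- side[idx, cols, drop = FALSE]
    names(out) <- paste0(cols, if (identical(side, a)) "1" else "2")
    rownames(out) <- NULL
    out
  }
  out <- cbind(data.frame(qname = qn, sample_id = sample_id,
                          stringsAsFactors = FALSE),
               end_cols(a, ia), end_cols(b, ib))
  out$mapped1[is.na(out$mapped1)] <- FALSE
  out$mapped2[is.na(out$mapped2)] <- FALSE
  for (s in c("1", "2")) {
    cl <- paste0("clipL", s); cr <- paste0("clipR", s)
    out[[cl]][is.na(out[[cl]])] <- 0L
    out[[cr]][is.na(out[[cr]])] <- 0L
  }
  out <- out[out$mapped1 | out$mapped2, , drop = FALSE]
  out$mate_unmapped <- xor(out$mapped1, out$mapped2)
  out$soft_clipped <- (out$clipL1 + out$clipR1 + out$clipL2 + out$clipR2) > 0L
  rownames(out) <- NULL
  out
}

empty_pairs_df <- function() {
  cols <- c("qname", "sample_id",
            paste0(rep(c("chrom", "start", "end", "strand", "mapq", "cigar",
                         "seq", "clipL", "clipR", "mapped"), 2),
                   rep(c("1", "2"), each = 10)),
            "mate_unmapped", "soft_clipped")
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                      cols), stringsAsFactors = FALSE)
  df
}

#' Classify read pairs as concordant, discordant or one-end-anchored
#'
#' A pair is concordant when both ends map to the same chromosome in
#' forward-reverse orientation (leftmost mate on the plus strand, rightmost
#' on the minus strand) with an outer span no larger than
#' `median_insert + 4 * insert_sd`; pairs mapped too far apart or in the
#' wrong orientation are discordant. Pairs with exactly one mapped end are
#' one-end-anchored.
#'
#' @param pairs Data frame from [read_pairs()].
#' @param stats A [library_stats()] object.
#' @return Character vector with values `"concordant"`, `"discordant"` or
#'   `"one_end_anchored"`.
#' @export
classify_pairs <- function(pairs, stats) {
  n <- nrow(pairs)
  if (n == 0) return(character(0))
  out <- rep("discordant", n)
  oea <- xor(pairs$mapped1, pairs$mapped2)
  out[oea] <- "one_end_anchored"
  both <- pairs$mapped1 & pairs$mapped2
  if (any(both)) {
    same <- both & (pairs$chrom1 == pairs$chrom2)
    lo <- pmin(pairs$start1, pairs$start2)
    hi <- pmax(pairs$end1, pairs$end2)
    span_ok <- (hi - lo) <= stats$median_insert + 4 * stats$insert_sd
    left_strand <- ifelse(pairs$start1 <= pairs$start2,
                          pairs$strand1, pairs$strand2)
    right_strand <- ifelse(pairs$start1 <= pairs$start2,
                           pairs$strand2, pairs$strand1)
    fr <- left_strand == "+" & right_strand == "-"
    conc <- !is.na(same) & same & span_ok & fr
    out[conc] <- "concordant"
  }
  out
}

#' @rdname classify_pairs
#' @param rec A single-row data.frame (one read pair).
#' @export
classify_pair <- function(rec, stats) classify_pairs(rec, stats)
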