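#' Insertion call table I/O
#'
#' Calls are plain data.frames with one row per candidate insertion locus.
#' Coordinates are 0-based half-open in memory, in the TSV, and in the
#' companion BED. Evidence columns (breakpoints, TSD, poly-A, junctions) may
#' be empty strings / NA before annotation.
#'
#' @name calls-io
NULL

call_table_columns <- c(
  "chrom", "start", "end", "gene_id", "n_support_total", "n_left", "n_right",
  "exons_hit", "samples", "filter_status", "bp5", "bp3", "tsd_seq",
  "polyA_len", "en_motif", "junctions")

empty_call_table <- function() {
  df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   gene_id = character(0), n_support_total = integer(0),
                   n_left = integer(0), n_right = integer(0),
                   exons_hit = character(0), samples = character(0),
                   filter_status = character(0), bp5 = integer(0),
                   bp3 = integer(0), tsd_seq = character(0),
                   polyA_len = integer(0), en_motif = character(0),
                   junctions = character(0), stringsAsFactors = FALSE)
  df
}

validate_call_table <- function(rows) {
  missing <- setdiff(call_table_columns, names(rows))
  if (length(missing) > 0)
    stop("call table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(rows) > 0) {
    if (any(rows$start > rows$end)) stop("call with start > end")
    if (any(rows$n_support_total != rows$n_left + rows$n_right))
      stop("n_support_total must equal n_left + n_right")
  }
  invisible(rows)
}

#' Write insertion calls as TSV plus companion BED
#'
#' @param rows Call table data.frame (see [empty_call_table()] for columns).
#' @param path Output TSV path; the BED is written next to it with extension
#'   `.bed`.
#' @return Character vector `c(tsv, bed)`, invisibly.
#' @export
write_calls <- function(rows, path) {
  validate_call_table(rows)
  rows <- rows[, call_table_columns, drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  bed <- sub("\\.[^./]*$", "", path)
  bed <- paste0(bed, ".bed")
  if (nrow(rows) > 0) {
    bed_df <- data.frame(rows$chrom, rows$start, rows$end,
                         paste0(rows$gene_id, "|",
                                sub(",.*$", "", rows$samples)),
                         rows$n_support_total, ".")
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed)
  }
  invisible(c(path, bed))
}

#' Read an insertion call TSV written by [write_calls()]
#'
#' @param path TSV path.
#' @return Call table data.frame.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("call table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(
                            chrom = "character", start = "integer",
                            end = "integer", gene_id = "character",
                            n_support_total = "integer", n_left = "integer",
                            n_right = "integer", exons_hit = "character",
                            samples = "character",
                            filter_status = "character", bp5 = "integer",
                            bp3 = "integer", tsd_seq = "character",
                            polyA_len = "integer", en_motif = "character",
                            junctions = "character"),
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("exons_hit", "samples", "filter_status", "tsd_seq",
                "en_motif", "junctions"))
    df[[col]][is.na(df[[col]])] <- ""
  validate_call_table(df)
  df
}

#' Read deletion intervals from a VCF
#'
#' Accepts symbolic `<DEL>` alleles (span from the INFO END field) and
#' explicit REF/ALT deletions (REF longer than ALT, deleted bases after the
#' shared leading base). Records whose span cannot be resolved are skipped
#' with a warning. Returned intervals are 0-based half-open and cover the
#' deleted bases only.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_deletions_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)            # 1-based POS
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(seq_len(n), function(i) {
    a <- VariantAnnotation::alt(vcf)[[i]]
    if (length(a) == 0) "" else as.character(a[[1]])
  }, character(1))
  info <- VariantAnnotation::info(vcf)
  endf <- if ("END" %in% names(info)) info$END else rep(NA_integer_, n)
  res <- lapply(seq_len(n), function(i) {
    if (identical(alt[i], "<DEL>")) {
      e <- endf[i]
      if (length(e) == 0 || is.na(e)) {
        warning("deletion record ", i, " without END skipped")
        return(NULL)
      }
      # deleted bases are POS+1 .. END (POS is the anchor base)
      return(c(pos[i], as.integer(e)))
    }
    if (nchar(ref[i]) > nchar(alt[i]) && nchar(alt[i]) >= 1 &&
        substr(ref[i], 1, nchar(alt[i])) == alt[i]) {
      # REF "ATTT" ALT "A" at POS p (1-based): deleted 0-based [p, p+3)
      return(c(pos[i] + nchar(alt[i]) - 1L,
               pos[i] + nchar(ref[i]) - 1L))
    }
    NULL  # SNV or unresolvable
  })
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) return(out)
  m <- do.call(rbind, res[keep])
  data.frame(chrom = chrom[keep], start = as.integer(m[, 1]),
             end = as.integer(m[, 2]), stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `path`, `population`, `pair_id`,
#' `tissue` (tumor/normal/NA). Only `sample_id` and `path` are mandatory.
#'
#' @param path TSV path.
#' @return Data frame with the five columns (missing ones filled with NA).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "path") %in% names(df)))
    stop("sample sheet needs at least columns sample_id and path")
  for (col in c("population", "pair_id", "tissue"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in sample sheet")
  df
}
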