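#' Gene models and the spliced transcript
#'
#' A gene model is the exon structure of one transcript: chromosome, strand,
#' and an ordered set of non-overlapping exon intervals. Internally every
#' interval is 0-based half-open; BED12 input/output is the only place the
#' convention is translated. Exon order index 1..k follows transcription
#' order, i.e. it runs right-to-left on the minus strand.
#'
#' @name gene-models
NULL

new_gene_model <- function(gene_id, chrom, strand, exons, cds_like = FALSE) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("gene ", gene_id, ": empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("gene ", gene_id, ": overlapping exons")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = unname(exons), cds_like = cds_like),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s)\n", x$gene_id,
              x$chrom, x$exons[1, 1], x$exons[nrow(x$exons), 2], x$strand,
              nrow(x$exons)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param gene A `gene_model`.
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
gene_span <- function(gene) c(gene$exons[1, 1], gene$exons[nrow(gene$exons), 2])

#' Load gene models from a BED12 file
#'
#' Exon intervals are reconstructed from the blockStarts/blockSizes columns
#' (via \pkg{rtracklayer}) and stored 0-based half-open. Records with
#' overlapping blocks are rejected with a warning; files whose blockCount
#' disagrees with the block lists fail to parse.
#'
#' @param path BED12 file.
#' @return Named list of `gene_model` objects (names are gene IDs).
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model BED12 not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED12 file '", path,
                                          "': ", conditionMessage(e)))
  if (length(gr) == 0) return(list())
  if (is.null(gr$blocks))
    stop("file '", path, "' lacks BED12 block columns")
  blk <- rtracklayer::blocks(gr)  # absolute, 1-based closed
  out <- list()
  for (i in seq_along(gr)) {
    ex <- blk[[i]]
    exons <- cbind(GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex))
    gid <- as.character(gr$name[i])
    gm <- tryCatch(
      new_gene_model(gid, as.character(GenomicRanges::seqnames(gr)[i]),
                     as.character(GenomicRanges::strand(gr)[i]), exons),
      error = function(e) {
        warning("record ", i, " (", gid, ") rejected: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(gm)) out[[gid]] <- gm
  }
  out
}

#' Write gene models as BED12
#'
#' Round-trips losslessly through [load_gene_models()].
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    s <- g$exons[1, 1]; e <- g$exons[nrow(g$exons), 2]
    sizes <- paste0(paste(g$exons[, 2] - g$exons[, 1], collapse = ","), ",")
    starts <- paste0(paste(g$exons[, 1] - s, collapse = ","), ",")
    paste(g$chrom, s, e, g$gene_id, 0L, g$strand, s, e, "0",
          nrow(g$exons), sizes, starts, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Number of exons of a gene model
#' @param gene A `gene_model`.
#' @return Integer exon count.
#' @export
n_exons <- function(gene) nrow(gene$exons)

#' Exon intervals in transcription order
#'
#' @param gene A `gene_model`.
#' @return Matrix of 0-based half-open intervals, row `i` being the i-th exon
#'   in transcription order (reversed genomic order on the minus strand).
#' @export
exons_in_tx_order <- function(gene) {
  ex <- gene$exons
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates the exon sequences in transcription order; minus-strand
#' genes yield the reverse complement of the genomic exon concatenation, so
#' the result always reads 5' to 3' in mRNA orientation.
#'
#' @param gene A `gene_model`.
#' @param genome A `genome_ref`.
#' @return Character transcript sequence.
#' @export
spliced_transcript <- function(gene, genome) {
  ex <- gene$exons
  parts <- vapply(seq_len(nrow(ex)), function(i)
    get_seq(genome, gene$chrom, ex[i, 1], ex[i, 2]), character(1))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Exon sequences in transcription order (mRNA strand)
#' @param gene A `gene_model`.
#' @param genome A `genome_ref`.
#' @return Character vector, element `i` the i-th exon's mRNA-strand sequence.
#' @export
exon_seqs_tx <- function(gene, genome) {
  ex <- exons_in_tx_order(gene)
  vapply(seq_len(nrow(ex)), function(i) {
    s <- get_seq(genome, gene$chrom, ex[i, 1], ex[i, 2])
    if (gene$strand == "-") revcomp(s) else s
  }, character(1))
}
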