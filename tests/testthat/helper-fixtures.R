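# Shared fixtures, all built in code at test time.

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- SAM/BAM construction ---------------------------------------------------

sam_header <- function(chrom_sizes) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
            as.integer(chrom_sizes)))
}

sam_line <- function(qname, flag, rname, pos1, mapq, cigar, rnext = "=",
                     pnext = 0, tlen = 0, seq = NULL) {
  if (is.null(seq)) {
    w <- sum(as.integer(regmatches(cigar,
      gregexpr("\\d+(?=[MIS=X])", cigar, perl = TRUE))[[1]]))
    seq <- strrep("A", max(w, 1))
  }
  paste(qname, flag, rname, pos1, mapq, cigar, rnext, pnext, tlen, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

# writes SAM lines to an indexed BAM, returns the BAM path
as_test_bam <- function(lines, chrom_sizes, dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  writeLines(c(sam_header(chrom_sizes), lines), sam)
  Rsamtools::asBam(sam, destination = file.path(dir, "reads"),
                   overwrite = TRUE, indexDestination = TRUE)
}

# --- pairs data.frame construction (bypasses BAM I/O) -----------------------

# one fully-mapped FR-style pair; coordinates 0-based half-open
mk_pair <- function(qname, chrom1, start1, strand1, chrom2, start2,
                    strand2, len = 100, mapq1 = 60, mapq2 = 60,
                    sample_id = "s1", seq1 = strrep("A", len),
                    seq2 = strrep("A", len)) {
  data.frame(qname = qname, sample_id = sample_id,
             chrom1 = chrom1, start1 = start1, end1 = start1 + len,
             strand1 = strand1, mapq1 = mapq1, cigar1 = paste0(len, "M"),
             seq1 = seq1, clipL1 = 0L, clipR1 = 0L, mapped1 = TRUE,
             chrom2 = chrom2, start2 = start2, end2 = start2 + len,
             strand2 = strand2, mapq2 = mapq2, cigar2 = paste0(len, "M"),
             seq2 = seq2, clipL2 = 0L, clipR2 = 0L, mapped2 = TRUE,
             mate_unmapped = FALSE, soft_clipped = FALSE,
             stringsAsFactors = FALSE)
}

mk_pairs <- function(...) do.call(rbind, list(...))

# discordant-pair rows as produced by harvest_discordants()
mk_dp <- function(gene_id, exon_index, distal_start, distal_strand,
                  distal_chrom = "chrB", sample_id = "s1", len = 100,
                  qname = NULL) {
  n <- max(length(exon_index), length(distal_start),
           length(distal_strand))
  if (is.null(qname)) qname <- sprintf("q%04d", seq_len(n))
  data.frame(sample_id = rep_len(sample_id, n),
             gene_id = rep_len(gene_id, n),
             exon_index = rep_len(exon_index, n),
             exo_chrom = "chrA", exo_start = 0L, exo_end = len,
             exo_strand = "+",
             distal_chrom = rep_len(distal_chrom, n),
             distal_start = rep_len(distal_start, n),
             distal_end = rep_len(distal_start, n) + len,
             distal_strand = rep_len(distal_strand, n),
             qname = qname, stringsAsFactors = FALSE)
}

# a cluster as produced by cluster_candidates()
mk_cluster <- function(dp) list(chrom = dp$distal_chrom[1],
                                gene_id = dp$gene_id[1], pairs = dp)

# read-level rows for breakpoint voting (as from scan_reads)
mk_clip_read <- function(start, end, seq, clipL = 0L, clipR = 0L,
                         mapq = 60) {
  data.frame(qname = sprintf("r%06d", sample.int(1e6, 1)), chrom = "chr1",
             start = start, end = end, strand = "+", mapq = mapq,
             cigar = "*", seq = seq, clipL = clipL, clipR = clipR,
             stringsAsFactors = FALSE)
}

# exactly-clipped junction reads for an insertion at site `pos` with TSD
# length `tsd` and inserted sequence `ins` (reference orientation):
# right-clipped reads end at pos+tsd and carry the insert 5' start;
# left-clipped reads start at pos and carry the insert 3' end.
mk_junction_reads <- function(genome, chrom, pos, tsd, ins,
                              n_each = 3, anchor = 60, clip = 40) {
  stopifnot(nchar(ins) >= clip)
  bp5 <- pos + tsd
  r5 <- do.call(rbind, lapply(seq_len(n_each), function(i) {
    a <- anchor + i  # vary anchor length, same clip position
    mk_clip_read(start = bp5 - a, end = bp5,
                 seq = paste0(get_seq(genome, chrom, bp5 - a, bp5),
                              substr(ins, 1, clip)),
                 clipR = clip)
  }))
  r3 <- do.call(rbind, lapply(seq_len(n_each), function(i) {
    a <- anchor + i
    mk_clip_read(start = pos, end = pos + a,
                 seq = paste0(substring(ins, nchar(ins) - clip + 1),
                              get_seq(genome, chrom, pos, pos + a)),
                 clipL = clip)
  }))
  rbind(r5, r3)
}

# --- tiny gene/genome fixture ----------------------------------------------

# deterministic 3-exon gene on a 6 kb chromosome
tiny_gene_fixture <- function(seed = 7, strand = "+") {
  genome <- genome_ref(c(chr1 = random_seq(6000, seed)))
  exons <- rbind(c(1000, 1200), c(1600, 1850), c(2400, 2600))
  gene <- retrocall:::new_gene_model("gA", "chr1", strand, exons)
  list(genome = genome, gene = gene, genes = list(gA = gene))
}

# --- cached benchmark simulation (built once per test run) ------------------

.bench_env <- new.env(parent = emptyenv())

benchmark_sim <- function() {
  if (!is.null(.bench_env$sim)) return(.bench_env$sim)
  dir <- file.path(tempdir(), "benchmark_sim")
  sim <- simulate_dataset(seed = 4242, out_dir = dir, n_spikes = 55,
                          coverage = 60,
                          chrom_sizes = c(chr1 = 150000, chr2 = 150000),
                          n_genes = 21)
  ss <- data.frame(sample_id = "g1", path = sim$bam,
                   stringsAsFactors = FALSE)
  sim$sample_sheet <- ss
  sim$calls60 <- discover(ss, sim$genes, sim$genome, sim$stats,
                          annotate = FALSE)
  .bench_env$sim <- sim
  sim
}

benchmark_calls_annotated <- function() {
  if (!is.null(.bench_env$annotated)) return(.bench_env$annotated)
  sim <- benchmark_sim()
  ann <- annotate_breakpoints(sim$calls60, sim$bam, sim$genome, sim$genes)
  .bench_env$annotated <- ann
  ann
}
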