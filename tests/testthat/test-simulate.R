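test_that("reference generation is reproducible and seed-sensitive", {
  a <- make_reference(1, chrom_sizes = c(c1 = 30000, c2 = 30000),
                      n_genes = 6)
  b <- make_reference(1, chrom_sizes = c(c1 = 30000, c2 = 30000),
                      n_genes = 6)
  expect_identical(as.character(a$genome$seqs), as.character(b$genome$seqs))
  expect_identical(lapply(a$genes, `[[`, "exons"),
                   lapply(b$genes, `[[`, "exons"))
  d <- make_reference(2, chrom_sizes = c(c1 = 30000, c2 = 30000),
                      n_genes = 6)
  expect_false(identical(as.character(a$genome$seqs),
                         as.character(d$genome$seqs)))
  # at least one single-exon gene when n_genes >= 5
  expect_true(any(vapply(a$genes, n_exons, integer(1)) == 1))
  # genes do not overlap
  for (ch in c("c1", "c2")) {
    spans <- do.call(rbind, lapply(Filter(function(g) g$chrom == ch,
                                          a$genes), gene_span))
    if (is.null(spans) || nrow(spans) < 2) next
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  }
  none <- make_reference(3, chrom_sizes = c(c1 = 20000), n_genes = 0)
  expect_length(none$genes, 0)
})

test_that("spliced transcripts concatenate exons in transcription order", {
  fx <- tiny_gene_fixture()
  tx <- spliced_transcript(fx$gene, fx$genome)
  expect_equal(nchar(tx), sum(fx$gene$exons[, 2] - fx$gene$exons[, 1]))
  expect_equal(tx, paste0(get_seq(fx$genome, "chr1", 1000, 1200),
                          get_seq(fx$genome, "chr1", 1600, 1850),
                          get_seq(fx$genome, "chr1", 2400, 2600)))
  fxm <- tiny_gene_fixture(strand = "-")
  expect_equal(spliced_transcript(fxm$gene, fxm$genome), revcomp(tx))
  one <- retrocall:::new_gene_model("g1", "chr1", "+",
                                    rbind(c(1000, 1200)))
  expect_equal(spliced_transcript(one, fx$genome),
               get_seq(fx$genome, "chr1", 1000, 1200))
})

test_that("spiking duplicates the target site around the insert", {
  fx <- tiny_gene_fixture()
  spec <- list(gene_id = "gA", chrom = "chr1", pos = 4000L, strand = "+",
               tsd_len = 15L, polyA_len = 20L, five_prime_truncation = 0L)
  res <- spike_retrocopy(fx$genome, spec, fx$genes)
  tx <- spliced_transcript(fx$gene, fx$genome)
  tsd <- get_seq(fx$genome, "chr1", 4000, 4015)
  left <- substr(res$allele, 4001, 4015)          # 0-based [4000,4015)
  expect_equal(left, tsd)
  ins_start <- 4015 + 1
  ins_len <- nchar(tx) + 20
  expect_equal(substr(res$allele, ins_start, ins_start + ins_len - 1),
               paste0(tx, strrep("A", 20)))
  right <- substr(res$allele, ins_start + ins_len,
                  ins_start + ins_len + 14)
  expect_equal(right, tsd)                        # duplicated on the right
  expect_equal(nchar(res$allele),
               fx$genome$sizes[["chr1"]] + ins_len + 15)
  expect_equal(res$truth$expected_junctions, "1-2;2-3")

  blunt <- spike_retrocopy(fx$genome, utils::modifyList(spec,
    list(tsd_len = 0L)), fx$genes)
  expect_equal(nchar(blunt$allele), fx$genome$sizes[["chr1"]] + ins_len)

  # truncation past the first junction drops it from the expectation
  trunc <- spike_retrocopy(fx$genome, utils::modifyList(spec,
    list(five_prime_truncation = 250L)), fx$genes)
  expect_equal(trunc$truth$expected_junctions, "2-3")

  expect_error(spike_retrocopy(fx$genome, utils::modifyList(spec,
    list(five_prime_truncation = nchar(tx))), fx$genes), "entire")
  expect_error(spike_retrocopy(fx$genome, utils::modifyList(spec,
    list(pos = 1500L)), fx$genes), "within the source gene")
})

test_that("read simulation is deterministic and hits target coverage", {
  ref <- make_reference(9, chrom_sizes = c(c1 = 20000), n_genes = 0,
                        out_dir = file.path(tempdir(), "readsim"))
  alleles <- c(c1 = as.character(ref$genome$seqs[[1]]))
  st <- library_stats(100, 500, 30)
  b1 <- file.path(tempdir(), "readsim", "r1.bam")
  b2 <- file.path(tempdir(), "readsim", "r2.bam")
  simulate_reads(alleles, 10, st, ref$fasta, b1, seed = 5)
  simulate_reads(alleles, 10, st, ref$fasta, b2, seed = 5)
  sb <- function(p) Rsamtools::scanBam(p,
    param = Rsamtools::ScanBamParam(what = c("qname", "seq")))[[1]]
  x <- sb(b1); y <- sb(b2)
  ox <- order(x$qname); oy <- order(y$qname)
  expect_identical(x$qname[ox], y$qname[oy])
  expect_identical(as.character(x$seq)[ox], as.character(y$seq)[oy])
  # ~ coverage * len / (2 * read_length) pairs
  expect_equal(length(unique(x$qname)), round(10 * 20000 / 200))
  # different seed -> different reads
  b3 <- file.path(tempdir(), "readsim", "r3.bam")
  simulate_reads(alleles, 10, st, ref$fasta, b3, seed = 6)
  expect_false(identical(sort(as.character(sb(b3)$seq)),
                         sort(as.character(x$seq))))
})

test_that("downsampling keeps pairs whole at the requested rate", {
  ref <- make_reference(9, chrom_sizes = c(c1 = 20000), n_genes = 0,
                        out_dir = file.path(tempdir(), "readsim2"))
  alleles <- c(c1 = as.character(ref$genome$seqs[[1]]))
  st <- library_stats(100, 500, 30)
  full <- file.path(tempdir(), "readsim2", "full.bam")
  simulate_reads(alleles, 20, st, ref$fasta, full, seed = 7)
  qn_of <- function(p) Rsamtools::scanBam(p,
    param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname
  all_qn <- qn_of(full)
  n_pairs <- length(unique(all_qn))

  same <- file.path(tempdir(), "readsim2", "same.bam")
  downsample_bam(full, 1, 1, same)
  expect_setequal(unique(qn_of(same)), unique(all_qn))

  half <- file.path(tempdir(), "readsim2", "half.bam")
  downsample_bam(full, 0.5, 2, half)
  qn <- qn_of(half)
  kept <- length(unique(qn))
  expect_gt(kept, stats::qbinom(1e-6, n_pairs, 0.5))
  expect_lt(kept, stats::qbinom(1 - 1e-6, n_pairs, 0.5))
  # mates are never orphaned
  cnt <- table(table(qn))
  expect_named(cnt, "2")
  expect_error(downsample_bam(full, 1.5, 1, half), "fraction")
})

test_that("call scoring counts TP/FP/FN with nearest-site assignment", {
  truths <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                       pos = seq(10000, 100000, length.out = 10),
                       stringsAsFactors = FALSE)
  mk <- function(gene, pos) {
    row <- empty_call_table()
    row[1, ] <- list("chr1", as.integer(pos), as.integer(pos), gene, 8L,
                     4L, 4L, "1,2", "s", "PASS", NA_integer_, NA_integer_,
                     "", NA_integer_, "", "")
    row
  }
  calls <- do.call(rbind, lapply(1:8, function(i)
    mk(paste0("g", i), truths$pos[i] + 20)))
  ev <- evaluate_calls(calls, truths)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(8L, 0L, 2L))
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 0.8)
  expect_equal(sum(ev$per_gene$n_detected), 8L)

  none <- evaluate_calls(calls[0, ], truths)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))

  # a call 150 bp away under slop 100 is an FP and leaves an FN
  off <- evaluate_calls(mk("g1", truths$pos[1] + 150),
                        truths[1, ], match_slop = 100)
  expect_equal(c(off$tp, off$fp, off$fn), c(0L, 1L, 1L))
  # gene identity is required even at zero distance
  wrong <- evaluate_calls(mk("g2", truths$pos[1]), truths[1, ])
  expect_equal(c(wrong$tp, wrong$fp), c(0L, 1L))
})
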