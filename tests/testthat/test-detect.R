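stats_sim <- library_stats(100, 500, 30)

test_that("pair classification follows span and FR orientation rules", {
  st <- library_stats(100, 300, 30)  # cut-off 300 + 4*30 = 420
  conc <- mk_pair("a", "chr1", 1000, "+", "chr1", 1210, "-")  # span 310
  expect_equal(classify_pair(conc, st), "concordant")
  xchr <- mk_pair("b", "chr1", 1000, "+", "chr2", 1210, "-")
  expect_equal(classify_pair(xchr, st), "discordant")
  far <- mk_pair("c", "chr1", 1000, "+", "chr1", 50900, "-")  # span 50000
  expect_equal(classify_pair(far, st), "discordant")
  # wrong orientation at proper distance is still discordant
  rf <- mk_pair("d", "chr1", 1000, "-", "chr1", 1210, "+")
  expect_equal(classify_pair(rf, st), "discordant")
  oea <- mk_pair("e", "chr1", 1000, "+", "chr1", 1210, "-")
  oea$mapped2 <- FALSE
  expect_equal(classify_pair(oea, st), "one_end_anchored")
})

test_that("harvesting keeps exactly-one-exonic, distal, high-MAPQ pairs", {
  fx <- tiny_gene_fixture()
  # exon 2 is [1600,1850); mate on another chromosome
  good <- mk_pair("g1", "chr1", 1650, "+", "chrB", 50000, "-")
  both_in_gene <- mk_pair("g2", "chr1", 1650, "+", "chr1", 2450, "-")
  lowq <- mk_pair("g3", "chr1", 1650, "+", "chrB", 50000, "-", mapq2 = 0)
  near <- mk_pair("g4", "chr1", 1650, "+", "chr1", 5000, "-")  # < 10 kb
  dp <- harvest_discordants(mk_pairs(good, both_in_gene, lowq, near),
                            fx$genes, stats_sim)
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$gene_id, "gA")
  expect_equal(dp$exon_index, 2L)
  expect_equal(dp$qname, "g1")
  # minus-strand gene: transcription order reverses the exon index
  fxm <- tiny_gene_fixture(strand = "-")
  dpm <- harvest_discordants(mk_pairs(good), fxm$genes, stats_sim)
  expect_equal(dpm$exon_index, 2L)  # middle exon stays index 2 of 3
  dpm2 <- harvest_discordants(
    mk_pairs(mk_pair("g5", "chr1", 1050, "+", "chrB", 50000, "-")),
    fxm$genes, stats_sim)
  expect_equal(dpm2$exon_index, 3L)  # leftmost exon is last in tx order
})

test_that("single-linkage clustering splits on gaps above the window", {
  one <- mk_dp("gA", 1:2, seq(10000, 10400, length.out = 8), "+")
  cl <- cluster_candidates(one, window = 500)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$pairs), 8L)
  two <- mk_dp("gA", 1:2, c(10000, 10100, 20100, 20200), c("+", "+", "-",
                                                           "-"))
  expect_length(cluster_candidates(two, window = 500), 2L)
  expect_length(cluster_candidates(two, window = 15000), 1L)
  expect_length(cluster_candidates(one[0, ]), 0L)
})

test_that("calling enforces support, per-side, exon-diversity and strand rules", {
  # 5 left (+) then 3 right (-) mappings, anchors in exons 1 and 3
  ok <- mk_dp("gA", c(1, 3), c(seq(9500, 9900, 100), seq(10050, 10250,
                                                         100)),
              c(rep("+", 5), rep("-", 3)))
  res <- call_insertion(mk_cluster(ok))
  expect_false(is.null(res$row))
  expect_equal(res$row$n_left, 5L)
  expect_equal(res$row$n_right, 3L)
  expect_equal(res$row$filter_status, "PASS")
  # interval = [max left end, min right start]
  expect_equal(res$row$start, 9900L + 100L)
  expect_equal(res$row$end, 10050L)

  seven <- ok[-1, ]
  expect_equal(call_insertion(mk_cluster(seven))$reason, "support")

  one_exon <- ok; one_exon$exon_index <- 1L
  expect_equal(call_insertion(mk_cluster(one_exon))$reason,
               "exon_diversity")

  one_side <- ok; one_side$distal_strand <- "+"
  expect_equal(call_insertion(mk_cluster(one_side))$reason,
               "side_support")

  flipped <- ok
  flipped$distal_strand <- rev(flipped$distal_strand)  # left group on -
  expect_equal(call_insertion(mk_cluster(flipped))$reason, "orientation")

  # identical-coordinate duplicates count once
  dup <- rbind(ok, ok)
  dup$qname <- sprintf("q%03d", seq_len(nrow(dup)))
  res_dup <- call_insertion(mk_cluster(dup))
  expect_equal(res_dup$row$n_support_total, 8L)
})

test_that("sample pooling concatenates with attribution and rejects duplicates", {
  a <- mk_dp("gA", c(1, 2), c(10000, 10100, 10200, 10300),
             c("+", "+", "-", "-"), sample_id = "sA")
  b <- mk_dp("gA", c(1, 2), c(10010, 10110, 10210, 10310),
             c("+", "+", "-", "-"), sample_id = "sB")
  pooled <- pool_samples(list(sA = a, sB = b))
  expect_equal(nrow(pooled), 8L)
  res <- call_insertion(mk_cluster(
    cluster_candidates(pooled, 500)[[1]]$pairs))
  expect_equal(res$row$samples, "sA,sB")
  # contribution requires reads: a sample with none is not listed
  res2 <- call_insertion(mk_cluster(cluster_candidates(
    pool_samples(list(sA = rbind(a, b2 <- transform(b, sample_id = "sA",
                                                    qname = paste0(qname,
                                                                   "x"))),
                      sB = a[0, ])), 500)[[1]]$pairs))
  expect_equal(res2$row$samples, "sA")
  expect_error(pool_samples(list(sA = a, sA = b)), "unique")
  expect_equal(nrow(pool_samples(list())), 0L)
})

test_that("emitted calls are invariant to input read order", {
  dp <- mk_dp("gA", rep(1:3, 4), seq(10000, 11100, 100),
              rep(c("+", "-"), each = 6))
  base <- cluster_candidates(dp, 500)
  calls_of <- function(d) {
    cl <- cluster_candidates(d, 500)
    do.call(rbind, Filter(Negate(is.null),
                          lapply(cl, function(x) call_insertion(x)$row)))
  }
  ref <- calls_of(dp)
  set.seed(42)
  for (i in 1:5) {
    perm <- dp[sample.int(nrow(dp)), ]
    expect_equal(calls_of(perm), ref)
  }
})

test_that("removing supporting pairs never creates calls", {
  # two well-separated loci; locus identity keyed at 5 kb resolution
  dp <- rbind(mk_dp("gA", rep(1:3, 4), seq(10000, 11100, 100),
                    rep(c("+", "-"), each = 6)),
              mk_dp("gA", rep(1:2, 5), seq(50000, 50900, 100),
                    rep(c("+", "-"), each = 5), qname = sprintf("r%02d",
                                                                1:10)))
  call_set <- function(d) {
    cl <- cluster_candidates(d, 500)
    rows <- Filter(Negate(is.null),
                   lapply(cl, function(x) call_insertion(x)$row))
    if (length(rows) == 0) character(0) else
      vapply(rows, function(r)
        paste(r$chrom, r$gene_id, r$start %/% 5000), character(1))
  }
  full <- call_set(dp)
  expect_length(full, 2L)
  set.seed(7)
  for (i in 1:25) {
    sub <- dp[sort(sample.int(nrow(dp), sample(0:nrow(dp), 1))), ,
              drop = FALSE]
    expect_true(all(call_set(sub) %in% full))
  }
})

test_that("PASS calls re-audit cleanly from their stored member pairs", {
  sim <- benchmark_sim()
  calls <- sim$calls60
  audit <- attr(calls, "audit")
  expect_equal(length(audit), nrow(calls))
  for (i in seq_len(nrow(calls))) {
    mem <- audit[[i]]
    dedup <- mem[!duplicated(paste(mem$distal_start, mem$distal_strand)), ]
    left <- dedup[dedup$distal_strand == "+", ]
    right <- dedup[dedup$distal_strand == "-", ]
    expect_gte(nrow(dedup), 8)
    expect_gte(nrow(left), 2)
    expect_gte(nrow(right), 2)
    expect_gte(length(unique(dedup$exon_index)), 2)
    expect_lte(max(left$distal_end), min(right$distal_start) + 30)
    expect_equal(calls$n_support_total[i], nrow(dedup))
  }
})
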