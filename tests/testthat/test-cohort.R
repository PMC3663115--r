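mk_call <- function(chrom, start, end, gene, samples) {
  row <- empty_call_table()
  row[1, ] <- list(chrom, as.integer(start), as.integer(end), gene,
                   8L, 4L, 4L, "1,2", samples, "PASS", NA_integer_,
                   NA_integer_, "", NA_integer_, "", "")
  row
}

test_that("profile matrices unify loci across samples", {
  calls <- rbind(mk_call("chr1", 1000, 1010, "gA", "s1,s2"),
                 mk_call("chr1", 5000, 5010, "gB", "s1"),
                 mk_call("chr2", 800, 810, "gC", "s2"))
  pm <- build_profile_matrix(calls)
  expect_equal(dim(pm$m), c(2L, 3L))
  expect_equal(sum(pm$m), 4L)  # shared locus + one private each
  single <- build_profile_matrix(mk_call("chr1", 1, 2, "gA", "sX"))
  expect_true(all(single$m))
  expect_equal(dim(single$m), c(1L, 1L))
  # same gene reported 100 bp apart merges into one locus
  off <- rbind(mk_call("chr1", 1000, 1010, "gA", "s1"),
               mk_call("chr1", 1100, 1110, "gA", "s2"))
  expect_equal(ncol(build_profile_matrix(off, merge_slop = 500)$m), 1L)
  expect_equal(ncol(build_profile_matrix(off, merge_slop = 50)$m), 2L)
})

test_that("Jaccard distance matches its definition and an independent oracle", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a", "b"), c("c", "d")), 1)
  # |union| = 10, |intersection| = 4 -> 0.6
  A <- paste0("l", 1:7)
  B <- paste0("l", 4:10)
  expect_equal(jaccard_distance(A, B), 0.6)
  expect_error(jaccard_distance(character(0), character(0)), "undefined")
  # oracle equivalence with vegan's binary Jaccard on random profiles
  set.seed(41)
  for (i in 1:20) {
    x <- stats::runif(8) < 0.5
    y <- stats::runif(8) < 0.5
    if (!any(x | y)) next
    mine <- jaccard_distance(which(x), which(y))
    ref <- as.numeric(vegan::vegdist(rbind(as.integer(x), as.integer(y)),
                                     method = "jaccard", binary = TRUE))
    expect_equal(mine, ref)
  }
})

test_that("Jaccard is a metric on a 6-locus universe (brute force)", {
  u <- paste0("L", 1:6)
  subsets <- lapply(0:63, function(m) u[bitwAnd(m, 2^(0:5)) > 0])
  nonempty <- subsets[-1]
  d <- matrix(NA_real_, 63, 63)
  for (i in 1:63) for (j in i:63)
    d[i, j] <- d[j, i] <- jaccard_distance(nonempty[[i]], nonempty[[j]])
  expect_true(all(diag(d) == 0))                      # identity
  expect_true(all(d == t(d)))                         # symmetry
  # identity of indiscernibles: zero distance only for equal sets
  zero <- which(d == 0, arr.ind = TRUE)
  expect_true(all(vapply(seq_len(nrow(zero)), function(r)
    setequal(nonempty[[zero[r, 1]]], nonempty[[zero[r, 2]]]),
    logical(1))))
  # triangle inequality over all ordered triples
  viol <- 0
  for (k in 1:63) {
    lhs <- d
    rhs <- outer(d[, k], d[k, ], `+`)
    viol <- viol + sum(lhs > rhs + 1e-12)
  }
  expect_equal(viol, 0)
})

test_that("profile clustering has forced topology and label invariance", {
  m <- matrix(FALSE, 3, 4, dimnames = list(c("s1", "s2", "s3"),
                                           paste0("L", 1:4)))
  m[c("s1", "s2"), 1:2] <- TRUE
  m["s3", 3:4] <- TRUE
  hc <- cluster_profiles(m)
  expect_equal(hc$height[1], 0)          # identical profiles join first
  expect_equal(hc$height[2], 1)          # disjoint set joins at 1
  grp <- stats::cutree(hc, 2)
  expect_equal(grp[["s1"]], grp[["s2"]])
  expect_false(grp[["s1"]] == grp[["s3"]])

  two <- cluster_profiles(m[1:2, , drop = FALSE])
  expect_equal(two$height, 0)
  expect_error(cluster_profiles(m[1, , drop = FALSE]), "two samples")

  perm <- m[c(3, 1, 2), ]
  coph <- stats::cophenetic(hc)
  coph_p <- stats::cophenetic(cluster_profiles(perm))
  ids <- rownames(m)
  expect_equal(as.matrix(coph)[ids, ids], as.matrix(coph_p)[ids, ids])

  nwk <- tempfile(fileext = ".nwk")
  write_profile_tree(hc, nwk)
  expect_match(readLines(nwk), "s1.*s2|s2.*s1")
})

test_that("population frequencies are carrier fractions", {
  m <- matrix(FALSE, 12, 2,
              dimnames = list(c(paste0("ceu", 1:10), "yri1", "yri2"),
                              c("LA", "LB")))
  m[1:3, "LA"] <- TRUE           # 3 of 10 CEU
  m[c("yri1", "yri2"), "LB"] <- TRUE
  pops <- stats::setNames(c(rep("CEU", 10), rep("YRI", 2)), rownames(m))
  f <- population_frequencies(m, pops)
  expect_equal(f["LA", "CEU"], 0.3)
  expect_equal(f["LA", "YRI"], 0)
  expect_equal(f["LB", "YRI"], 1)
  expect_true(all(f >= 0 & f <= 1))
  expect_error(population_frequencies(m, pops[-1]), "label")
})

test_that("somatic calls require zero support in normal and cohort", {
  tumor <- mk_call("chr5", 20000, 20010, "gA", "t1")
  none <- mk_dp("gX", 1, 999000, "+")[0, ]
  expect_equal(nrow(somatic_calls(tumor, none, none)), 1L)
  # a single read pair in the matched normal vetoes
  veto <- mk_dp("gA", 1, 20100, "+", distal_chrom = "chr5",
                sample_id = "n1")[1, ]
  expect_equal(nrow(somatic_calls(tumor, veto, none)), 0L)
  # support for another gene at the locus does not veto
  other_gene <- transform(veto, gene_id = "gB")
  expect_equal(nrow(somatic_calls(tumor, other_gene, none)), 1L)
  # cohort support vetoes too, and adding cohort samples only shrinks
  cohort <- transform(veto, sample_id = "z9")
  expect_equal(nrow(somatic_calls(tumor, none, cohort)), 0L)
  expect_equal(nrow(somatic_calls(tumor[0, ], none, none)), 0L)
  expect_error(somatic_calls(tumor, NULL, none), "normal")
})

test_that("reference retrocopies come from contained, homologous deletions", {
  fx <- tiny_gene_fixture()
  tx <- spliced_transcript(fx$gene, fx$genome)
  chr <- as.character(fx$genome$seqs[["chr1"]])
  # plant a full-length transcript copy (a reference retrocopy) at 3500
  g2 <- genome_ref(c(chr1 = paste0(substr(chr, 1, 3500), tx,
                                   substr(chr, 3501, nchar(chr)))))
  pg_len <- nchar(tx)
  pg <- data.frame(chrom = "chr1", start = 3500L,
                   end = 3500L + pg_len, source_gene = "gA",
                   stringsAsFactors = FALSE)
  contained_2x <- data.frame(chrom = "chr1",
                             start = as.integer(3500 - pg_len / 2),
                             end = as.integer(3500 + 1.5 * pg_len))
  out <- reference_grips(contained_2x, pg, g2, fx$genes)
  expect_equal(nrow(out), 1L)
  expect_equal(out$source_gene, "gA")
  # deletion 4x the annotation length is rejected
  too_big <- data.frame(chrom = "chr1",
                        start = as.integer(3500 - 1.5 * pg_len),
                        end = as.integer(3500 + 2.5 * pg_len))
  expect_equal(nrow(reference_grips(too_big, pg, g2, fx$genes)), 0L)
  # containing deletion without homology to the source is rejected
  pg_far <- data.frame(chrom = "chr1", start = 4800L, end = 5200L,
                       source_gene = "gA", stringsAsFactors = FALSE)
  del_far <- data.frame(chrom = "chr1", start = 4700L, end = 5400L)
  expect_equal(nrow(reference_grips(del_far, pg_far, fx$genome,
                                    fx$genes)), 0L)
  # unresolvable source gene -> warning, skipped
  pg_bad <- transform(pg, source_gene = "nope")
  expect_warning(out2 <- reference_grips(contained_2x, pg_bad, g2,
                                         fx$genes), "source gene")
  expect_equal(nrow(out2), 0L)
})
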