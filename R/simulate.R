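#' Spike-in simulation of processed retrocopy insertions
#'
#' Builds a synthetic multi-chromosome genome with multi- and single-exon
#' gene models, spikes processed-transcript insertions carrying the
#' hallmarks of retrotransposition (spliced exons, optional 5' truncation,
#' poly-A tail, exact target site duplication), simulates FR paired reads
#' over the modified alleles, realigns them to the unmodified reference
#' with \command{bwa mem}, and scores calls against the recorded truth.
#'
#' @name simulate
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference genome with gene models
#'
#' Gene structures are placed without overlap, separated by at least
#' `gene_gap` bp; when `n_genes >= 5` the last gene is single-exon so the
#' known single-exon blind spot of exon-diversity calling can be exercised.
#' Reproducible from `seed`.
#'
#' @param seed Integer RNG seed.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param n_genes Number of gene models.
#' @param exon_count_range,exon_len_range,intron_len_range Integer ranges
#'   for gene structure sampling.
#' @param gene_gap Minimum distance between genes and to chromosome ends.
#' @param out_dir Optional directory; when given, `genome.fa` and
#'   `genes.bed12` are written there.
#' @return List with `genome` (a `genome_ref`), `genes` (named list of
#'   `gene_model`), and file paths `fasta`/`bed` when `out_dir` is given.
#' @export
make_reference <- function(seed, chrom_sizes = c(chr1 = 120000,
                                                 chr2 = 120000),
                           n_genes = 20, exon_count_range = c(3, 6),
                           exon_len_range = c(150, 400),
                           intron_len_range = c(300, 800),
                           gene_gap = 2000, out_dir = NULL) {
  res <- with_seed(seed, {
    seqs <- vapply(chrom_sizes, random_dna, character(1))
    names(seqs) <- names(chrom_sizes)
    genes <- list()
    occupied <- lapply(chrom_sizes, function(x) cbind(integer(0),
                                                     integer(0)))
    for (gi in seq_len(n_genes)) {
      single <- (n_genes >= 5 && gi == n_genes)
      k <- if (single) 1L else
        sample(seq(exon_count_range[1], exon_count_range[2]), 1)
      elens <- sample(seq(exon_len_range[1], exon_len_range[2]), k,
                      replace = TRUE)
      ilens <- if (k > 1)
        sample(seq(intron_len_range[1], intron_len_range[2]), k - 1,
               replace = TRUE) else integer(0)
      span <- sum(elens) + sum(ilens)
      placed <- FALSE
      for (try in 1:1000) {
        ch <- sample(names(chrom_sizes), 1)
        maxs <- chrom_sizes[[ch]] - span - gene_gap
        if (maxs <= gene_gap) next
        s <- sample(seq(gene_gap, maxs), 1)
        occ <- occupied[[ch]]
        if (nrow(occ) > 0 &&
            any(occ[, 1] < s + span + gene_gap & occ[, 2] > s - gene_gap))
          next
        starts <- s + cumsum(c(0L, head_int(elens, -1) +
                                 if (k > 1) ilens else integer(0)))
        exons <- cbind(starts, starts + elens)
        gid <- sprintf("gene%02d", gi)
        genes[[gid]] <- new_gene_model(gid, ch, sample(c("+", "-"), 1),
                                       exons)
        occupied[[ch]] <- rbind(occ, c(s, s + span))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place gene ", gi,
                        ": genome too small for the requested structure")
    }
    list(seqs = seqs, genes = genes)
  })
  out <- list(genome = genome_ref(res$seqs), genes = res$genes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$fasta <- file.path(out_dir, "genome.fa")
    out$bed <- file.path(out_dir, "genes.bed12")
    write_fasta(res$seqs, out$fasta)
    write_gene_models(res$genes, out$bed)
  }
  out
}

head_int <- function(x, n) if (length(x) == 0) x else utils::head(x, n)

#' Spike one processed retrocopy insertion into a chromosome sequence
#'
#' The modified allele is `ref[0, pos + tsd_len) + insert + ref[pos, ...)`,
#' so the `tsd_len` reference bases at the site flank the insert on both
#' sides (an exact target site duplication). The insert is the spliced
#' transcript minus `five_prime_truncation` leading bases, followed by
#' `polyA_len` adenines; for `strand = "-"` the whole insert is
#' reverse-complemented.
#'
#' @param genome A `genome_ref` (the unmodified reference).
#' @param spec List with `gene_id`, `chrom`, `pos` (0-based insertion
#'   site), `strand`, `tsd_len`, `polyA_len`, `five_prime_truncation`.
#' @param genes Named list of `gene_model` objects (must contain the source
#'   gene).
#' @return List with `allele` (modified chromosome sequence) and `truth`
#'   (one-row data.frame: spec fields plus `insert_len` and
#'   `expected_junctions` such as `"1-2;2-3"`).
#' @export
spike_retrocopy <- function(genome, spec, genes) {
  gene <- genes[[spec$gene_id]]
  if (is.null(gene)) stop("unknown source gene: ", spec$gene_id)
  sp <- gene_span(gene)
  if (spec$chrom == gene$chrom && spec$pos >= sp[1] && spec$pos < sp[2])
    stop("insertion position lies within the source gene span")
  n <- genome$sizes[[spec$chrom]]
  if (spec$pos < 0 || spec$pos + spec$tsd_len > n)
    stop("insertion position out of bounds")
  tx <- spliced_transcript(gene, genome)
  if (spec$five_prime_truncation >= nchar(tx))
    stop("truncation removes the entire transcript")
  body <- substring(tx, spec$five_prime_truncation + 1L)
  ins <- paste0(body, strrep("A", spec$polyA_len))
  if (spec$strand == "-") ins <- revcomp(ins)
  chrom_seq <- as.character(genome$seqs[[spec$chrom]])
  allele <- paste0(substring(chrom_seq, 1L, spec$pos + spec$tsd_len),
                   ins, substring(chrom_seq, spec$pos + 1L))
  exlen <- exons_in_tx_order(gene)[, 2] - exons_in_tx_order(gene)[, 1]
  bounds <- cumsum(exlen)
  surviving <- which(bounds[-length(bounds)] > spec$five_prime_truncation)
  junc <- if (length(surviving) > 0)
    paste(paste0(surviving, "-", surviving + 1L), collapse = ";") else ""
  truth <- data.frame(gene_id = spec$gene_id, chrom = spec$chrom,
                      pos = spec$pos, strand = spec$strand,
                      tsd_len = spec$tsd_len, polyA_len = spec$polyA_len,
                      five_prime_truncation = spec$five_prime_truncation,
                      insert_len = nchar(ins),
                      expected_junctions = junc, stringsAsFactors = FALSE)
  list(allele = allele, truth = truth)
}

# apply many spikes; positions are reference coordinates, applied
# right-to-left per chromosome so earlier coordinates stay valid
apply_spikes <- function(genome, specs, genes) {
  seqs <- vapply(names(genome$sizes), function(ch)
    as.character(genome$seqs[[ch]]), character(1))
  truths <- list()
  ord <- order(vapply(specs, `[[`, character(1), "chrom"),
               -vapply(specs, `[[`, numeric(1), "pos"))
  for (i in ord) {
    spec <- specs[[i]]
    # splice from the untouched reference, insert into the growing allele
    res <- spike_retrocopy(genome, spec, genes)
    cur <- seqs[[spec$chrom]]
    tx_ins <- substring(res$allele, spec$pos + spec$tsd_len + 1L,
                        nchar(res$allele) - (genome$sizes[[spec$chrom]] -
                                               spec$pos))
    seqs[[spec$chrom]] <- paste0(
      substring(cur, 1L, spec$pos + spec$tsd_len), tx_ins,
      substring(cur, spec$pos + 1L))
    truths[[length(truths) + 1L]] <- res$truth
  }
  list(alleles = seqs, truth = do.call(rbind, rev(truths)))
}

#' Simulate FR paired-end reads and realign them to the reference
#'
#' Fragments are sampled uniformly over each allele sequence with lengths
#' drawn from Normal(`median_insert`, `insert_sd`); each fragment yields a
#' forward read from its left end and a reverse-complemented read from its
#' right end (`read_length` bp each), with independent substitution errors
#' at `error_rate`. Reads are aligned back to the unmodified reference with
#' \command{bwa mem} (single-threaded, deterministic), then sorted and
#' indexed.
#'
#' @param alleles Named character vector of allele sequences (one per
#'   chromosome, typically from [spike_retrocopy()]).
#' @param coverage Mean read coverage (bp of read per bp of allele).
#' @param stats A [library_stats()] object.
#' @param ref_fasta Path to the reference FASTA to align against.
#' @param out_bam Output BAM path (sorted; a `.bai` index is created).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer RNG seed; the read set is deterministic given it.
#' @return `out_bam`, invisibly.
#' @export
simulate_reads <- function(alleles, coverage, stats, ref_fasta, out_bam,
                           error_rate = 0.001, seed = 1) {
  if (coverage <= 0) stop("coverage must be positive")
  if (Sys.which("bwa") == "")
    stop("bwa not found on PATH; it is required for read realignment")
  rl <- stats$read_length
  fq <- with_seed(seed, {
    r1 <- character(0); r2 <- character(0); nm <- character(0)
    for (ch in names(alleles)) {
      len <- nchar(alleles[[ch]])
      npairs <- round(coverage * len / (2 * rl))
      if (npairs < 1) next
      frag <- pmax(2 * rl, round(stats::rnorm(npairs, stats$median_insert,
                                              stats$insert_sd)))
      frag <- pmin(frag, len)
      pos <- floor(stats::runif(npairs, 0, len - frag + 1))
      left <- substring(alleles[[ch]], pos + 1L, pos + rl)
      rightseq <- substring(alleles[[ch]], pos + frag - rl + 1L,
                            pos + frag)
      right <- revcomp_many(rightseq)
      r1 <- c(r1, left); r2 <- c(r2, right)
      nm <- c(nm, sprintf("frag_%s_%06d", ch, seq_len(npairs)))
    }
    list(r1 = add_seq_errors(r1, error_rate),
         r2 = add_seq_errors(r2, error_rate), nm = nm)
  })
  if (length(fq$nm) == 0) stop("no read pairs generated; raise coverage")
  tmp <- tempfile("simreads")
  fq1 <- paste0(tmp, "_1.fq"); fq2 <- paste0(tmp, "_2.fq")
  qual <- strrep("I", rl)
  writeLines(paste0("@", fq$nm, "\n", fq$r1, "\n+\n", qual), fq1)
  writeLines(paste0("@", fq$nm, "\n", fq$r2, "\n+\n", qual), fq2)
  if (!file.exists(paste0(ref_fasta, ".bwt"))) {
    rc <- system2("bwa", c("index", shQuote(ref_fasta)), stdout = FALSE,
                  stderr = FALSE)
    if (rc != 0) stop("bwa index failed")
  }
  sam <- paste0(tmp, ".sam")
  rc <- system2("bwa", c("mem", "-t", "1", shQuote(ref_fasta),
                         shQuote(fq1), shQuote(fq2)),
                stdout = sam, stderr = FALSE)
  if (rc != 0) stop("bwa mem failed")
  dest <- sub("\\.bam$", "", out_bam)
  Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
  unlink(c(fq1, fq2, sam))
  invisible(out_bam)
}

add_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  nb <- length(reads) * rl
  nerr <- stats::rbinom(1, nb, error_rate)
  if (nerr == 0) return(reads)
  at <- sample.int(nb, nerr)
  ri <- (at - 1L) %/% rl + 1L
  pi <- (at - 1L) %% rl + 1L
  subs <- sample(c("A", "C", "G", "T"), nerr, replace = TRUE)
  for (e in seq_len(nerr))
    substr(reads[ri[e]], pi[e], pi[e]) <- subs[e]
  reads
}

#' Downsample a BAM by whole read pairs
#'
#' Each query name is kept independently with probability `fraction`; mates
#' are kept or dropped together, so no read is orphaned.
#'
#' @param bam Input indexed BAM.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer RNG seed.
#' @param out_bam Output BAM path (indexed).
#' @return `out_bam`, invisibly.
#' @export
downsample_bam <- function(bam, fraction, seed, out_bam) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  qn <- unique(Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname)
  keep <- with_seed(seed, qn[stats::runif(length(qn)) <= fraction])
  keepenv <- new.env(parent = emptyenv())
  for (q in keep) assign(q, TRUE, envir = keepenv)
  rules <- S4Vectors::FilterRules(list(pairkeep = function(x)
    vapply(x$qname, exists, logical(1), envir = keepenv,
           inherits = FALSE)))
  dest <- Rsamtools::filterBam(bam, destination = out_bam,
    filter = rules,
    param = Rsamtools::ScanBamParam(what = "qname"),
    indexDestination = TRUE)
  invisible(dest)
}

#' Score calls against spike-in truth
#'
#' A truth is matched when a call of the same source gene on the same
#' chromosome lies within `match_slop` bp of the spiked site; each call is
#' assigned to at most one (its nearest) truth. Precision is
#' TP / (TP + FP) (undefined when no calls were made), recall
#' TP / (TP + FN).
#'
#' @param calls Call table data.frame (typically the PASS rows).
#' @param truths Truth data.frame from [spike_retrocopy()] /
#'   [simulate_dataset()].
#' @param match_slop Site-matching tolerance (bp).
#' @return List with `tp`, `fp`, `fn`, `precision` (NA when undefined),
#'   `recall`, and `per_gene` recall table.
#' @export
evaluate_calls <- function(calls, truths, match_slop = 100) {
  nT <- nrow(truths)
  assigned <- rep(NA_integer_, nrow(calls))
  if (nrow(calls) > 0 && nT > 0) {
    for (i in seq_len(nrow(calls))) {
      elig <- which(truths$gene_id == calls$gene_id[i] &
                      truths$chrom == calls$chrom[i])
      if (length(elig) == 0) next
      d <- vapply(elig, function(t) {
        p <- truths$pos[t]
        if (p >= calls$start[i] && p <= calls$end[i]) 0
        else min(abs(p - calls$start[i]), abs(p - calls$end[i]))
      }, numeric(1))
      j <- which.min(d)
      if (d[j] <= match_slop) assigned[i] <- elig[j]
    }
  }
  tp_truths <- unique(assigned[!is.na(assigned)])
  tp <- length(tp_truths)
  fp <- sum(is.na(assigned))
  fn <- nT - tp
  per_gene <- NULL
  if (nT > 0) {
    det <- truths$gene_id[tp_truths]
    per_gene <- as.data.frame(table(gene_id = truths$gene_id),
                              stringsAsFactors = FALSE)
    names(per_gene)[2] <- "n_spiked"
    dtab <- table(det)
    per_gene$n_detected <- as.integer(dtab[per_gene$gene_id])
    per_gene$n_detected[is.na(per_gene$n_detected)] <- 0L
    per_gene$recall <- per_gene$n_detected / per_gene$n_spiked
  }
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (nT == 0) NA_real_ else tp / nT,
       per_gene = per_gene)
}

#' One-stop simulation of a spiked benchmark dataset
#'
#' Generates a reference (see [make_reference()]), samples spike
#' specifications (TSD length uniform on [5, 25] bp, poly-A tail uniform on
#' [8, 30] bp, half the inserts 5'-truncated by up to 40% of the
#' transcript), applies them, and simulates reads at `coverage`. Spike
#' sites are kept clear of the source gene span (by the harvesting distal
#' flank plus margin), of all exons, and of each other, mirroring
#' interspersed germline insertions.
#'
#' @param seed Integer RNG seed driving every random choice.
#' @param out_dir Output directory for `genome.fa`, `genes.bed12`,
#'   `reads.bam`, `truth.tsv`.
#' @param n_spikes Number of insertions to spike.
#' @param coverage Read coverage of the simulated sample.
#' @param spike_gene_class `"multi"` (default) restricts source genes to
#'   multi-exon models, `"single"` to single-exon ones, `"any"` uses all.
#' @param stats A [library_stats()] object; the default emulates 100 bp
#'   ends with a 300 bp unsequenced middle.
#' @param error_rate Per-base substitution error rate.
#' @param ... Passed to [make_reference()].
#' @return List with `genome`, `genes`, `truth`, `bam`, `fasta`, `bed`,
#'   `stats`.
#' @export
simulate_dataset <- function(seed, out_dir, n_spikes = 55, coverage = 60,
                             spike_gene_class = c("multi", "single",
                                                  "any"),
                             stats = library_stats(100, 500, 30),
                             error_rate = 0.001, ...) {
  spike_gene_class <- match.arg(spike_gene_class)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(seed, out_dir = out_dir, ...)
  genes <- ref$genes
  genome <- ref$genome
  pool <- switch(spike_gene_class,
    multi = names(genes)[vapply(genes, n_exons, integer(1)) >= 2],
    single = names(genes)[vapply(genes, n_exons, integer(1)) == 1],
    any = names(genes))
  if (length(pool) == 0) stop("no source genes of the requested class")
  exons <- exon_index_table(genes)
  specs <- with_seed(seed + 1L, {
    out <- list()
    sites <- data.frame(chrom = character(0), pos = numeric(0))
    for (i in seq_len(n_spikes)) {
      gid <- sample(pool, 1)
      g <- genes[[gid]]
      sp <- gene_span(g)
      placed <- FALSE
      for (try in 1:2000) {
        ch <- sample(names(genome$sizes), 1)
        pos <- floor(stats::runif(1, 600, genome$sizes[[ch]] - 600))
        if (ch == g$chrom && pos > sp[1] - 11000 && pos < sp[2] + 11000)
          next
        exch <- exons[exons$chrom == ch, , drop = FALSE]
        if (nrow(exch) > 0 &&
            any(pos > exch$start - 200 & pos < exch$end + 200)) next
        prev <- sites[sites$chrom == ch, , drop = FALSE]
        if (nrow(prev) > 0 && any(abs(prev$pos - pos) < 2500)) next
        sites[nrow(sites) + 1L, ] <- list(ch, pos)
        tx_len <- sum(g$exons[, 2] - g$exons[, 1])
        trunc <- if (stats::runif(1) < 0.5) 0L else
          floor(stats::runif(1, 0, 0.4 * tx_len))
        out[[i]] <- list(gene_id = gid, chrom = ch, pos = pos,
                         strand = sample(c("+", "-"), 1),
                         tsd_len = sample(5:25, 1),
                         polyA_len = sample(8:30, 1),
                         five_prime_truncation = trunc)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place spike ", i)
    }
    out
  })
  spiked <- apply_spikes(genome, specs, genes)
  bam <- file.path(out_dir, "reads.bam")
  simulate_reads(spiked$alleles, coverage, stats, ref$fasta, bam,
                 error_rate = error_rate, seed = seed + 2L)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(spiked$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(genome = genome, genes = genes, truth = spiked$truth, bam = bam,
       fasta = ref$fasta, bed = ref$bed, truth_tsv = truth_path,
       stats = stats)
}
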